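# Poisson arrival simulation and line-scan rendering.

test_that("simulateArrivals matches Poisson counting statistics", {
  # vanishing window: zero or occasionally one event, handled cleanly
  tiny <- simulateArrivals(1, 0.5, duration = 1e-9, seed = 1)
  expect_lte(nrow(eventTable(tiny)), 1)

  # mean count over 50 seeds within 3 sqrt(1e4) of lambda * duration = 1e4
  counts <- vapply(1:50, function(s)
    nrow(eventTable(simulateArrivals(100, 0.5, duration = 100, seed = s))),
    numeric(1))
  expect_lt(abs(mean(counts) - 1e4), 3 * sqrt(1e4))

  # binomial labeling at r = 0.6 over 1e4 events
  tr <- simulateArrivals(100, 0.6, nEvents = 1e4, seed = 2)
  frac <- mean(eventTable(tr)$is_target)
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 1e4))

  # exponential gaps have the right mean
  gaps <- diff(eventTable(tr)$time_s)
  expect_lt(abs(mean(gaps) - 1 / 100), 3 * (1 / 100) / sqrt(length(gaps)))

  expect_error(simulateArrivals(-1, 0.5, 1), "rate")
  expect_error(simulateArrivals(10, 0.5, -1), "duration")
  expect_error(simulateArrivals(10, 1.5, 1), "targetFraction")
})

test_that("simulateArrivals is reproducible for a fixed seed", {
  a <- simulateArrivals(50, 0.6, duration = 2, seed = 99)
  b <- simulateArrivals(50, 0.6, duration = 2, seed = 99)
  expect_identical(eventTable(a), eventTable(b))
})

test_that("renderStream geometry and noiseless signal are exact", {
  cfg <- acquisitionConfig(noiseSigma = 0)
  basis <- defaultBasis()
  lp <- linePeriod(cfg)

  # empty truth -> pure zeros (noiseless) and flat FSC
  none <- simulateArrivals(1, 0.5, duration = 1e-9, seed = 3)
  none@events <- none@events[0, ]
  acq <- renderStream(none, basis, cfg, duration = 50 * lp)
  expect_true(all(acq$stream@samples == 0))
  expect_true(all(acq$fsc@values == 0))

  # one noiseless specimen: every in-support pixel equals responses %*% c
  tr <- oneSpecimen(100 * lp, radius = 3, species = "PMMA",
                    duration = 200 * lp)
  acq <- renderStream(tr, basis, cfg, duration = 200 * lp)
  s <- acq$stream@samples
  hit <- which(s[, , 1] != 0 | s[, , 2] != 0 | s[, , 3] != 0 |
                 s[, , 4] != 0, arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  expected <- drop(responses(basis) %*% c(PS = 0, PMMA = 1))
  for (k in 1:4) {
    vals <- s[, , k][s[, , 4] != 0]   # color 4 has the weakest PMMA signal
    expect_true(all(abs(vals - expected[k]) < 1e-12))
  }
  # unmixImage recovers the concentrations exactly on the support
  dec <- unmixImage(s, basis)
  expect_true(all(abs(dec[, , "PMMA"][s[, , 1] != 0] - 1) < 1e-9))

  # FSC pulse duration = 2 R / v: radius 3 um at 0.04 m/s = 150 us ~ 7 lines
  expect_equal(sum(acq$fsc@values > 0), 7)
  expect_equal(max(acq$fsc@values), 2 * 3)  # full chord at the center line
})

test_that("rendering is bit-identical for identical seeds and configs", {
  cfg <- acquisitionConfig(seed = 7)
  basis <- defaultBasis()
  tr <- simulateArrivals(200, 0.6, duration = 0.01, seed = 4)
  a <- renderStream(tr, basis, cfg)
  b <- renderStream(tr, basis, cfg)
  expect_identical(a$stream@samples, b$stream@samples)
  expect_identical(a$fsc@values, b$fsc@values)
})

test_that("integrated noiseless signal matches the analytic disk area", {
  cfg <- acquisitionConfig(noiseSigma = 0)
  basis <- defaultBasis()
  lp <- linePeriod(cfg)
  px <- flowPitch(cfg) * lateralPitch(cfg)   # um^2 per raw pixel
  for (R in c(3, 4.5, 6)) {                  # >= 3 px in every direction
    tr <- oneSpecimen(300 * lp, radius = R, duration = 600 * lp)
    s <- renderStream(tr, basis, cfg, duration = 600 * lp)$stream@samples
    sPMMA <- drop(responses(basis) %*% c(0, 1))
    for (k in which(sPMMA > 0.1)) {
      got <- sum(s[, , k])
      want <- pi * R^2 / px * sPMMA[k]
      expect_lt(abs(got - want) / want, 0.05)
    }
  }
})

test_that("FSC pulse count equals specimen count for separated arrivals", {
  cfg <- acquisitionConfig(noiseSigma = 0)
  basis <- defaultBasis()
  lp <- linePeriod(cfg)
  n <- 8
  ev <- data.frame(event_id = seq_len(n) - 1L,
                   time_s = seq(0.002, by = 0.002, length.out = n),
                   species = "PMMA", is_target = TRUE, radius_um = 3,
                   lateral_offset_um = 0, stringsAsFactors = FALSE)
  tr <- new("GroundTruth", events = ev, rate = 500, targetFraction = 1,
            duration = 0.02)
  fsc <- renderStream(tr, basis, cfg)$fsc
  pulses <- sum(diff(c(FALSE, fsc@values > 0)) == 1)
  expect_equal(pulses, n)
})

test_that("specimens outside the lateral field of view are rejected", {
  cfg <- acquisitionConfig(noiseSigma = 0)
  tr <- oneSpecimen(0.001, radius = 3, offset = 10.5)
  expect_error(renderStream(tr, defaultBasis(), cfg), "field of view")
})

test_that("droplet texture adds local signal without changing support", {
  cfg <- acquisitionConfig(noiseSigma = 0)
  basis <- defaultBasis()
  lp <- linePeriod(cfg)
  tr <- oneSpecimen(100 * lp, radius = 6, duration = 200 * lp)
  trD <- addDroplets(tr, nDroplets = 2, multiplier = 3, seed = 8)
  plain <- renderStream(tr, basis, cfg, duration = 200 * lp)$stream@samples
  drop_ <- renderStream(trD, basis, cfg, duration = 200 * lp)$stream@samples
  expect_true(all(drop_ >= plain - 1e-12))
  expect_gt(max(drop_ - plain), 1)  # droplets triple the local signal
  expect_identical(drop_ > 0, plain > 0)
})
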