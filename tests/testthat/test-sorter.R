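# The sorter displacement rules, the 32-scenario analytic model, the
# Monte-Carlo event-stream simulator, and the metrics.

test_that("intervalProb is the Poisson short-interval probability", {
  expect_equal(intervalProb(100, 0), 0)
  expect_equal(intervalProb(log(2) / 1.5e-3, 1.5e-3), 0.5)
  expect_equal(intervalProb(50.2, 1.5e-3), 1 - exp(-0.0753))
  expect_error(intervalProb(-1, 1e-3), ">= 0")
})

test_that("classifyScenario reproduces the narrated outcomes", {
  # an isolated nontarget is never touched
  expect_equal(classifyScenario(FALSE, FALSE, FALSE, FALSE, FALSE), "TN")
  expect_equal(classifyScenario(FALSE, FALSE, FALSE, TRUE, TRUE), "TN")
  # scenario 7: target, nontarget, target with a short preceding gap and a
  # long following gap -> the preceding push carries the nontarget along,
  # the later opposite push misses it -> false positive
  expect_equal(classifyScenario(TRUE, FALSE, TRUE, TRUE, FALSE), "FP")
  # its counterfactual: with a long preceding gap nothing displaces it
  expect_equal(classifyScenario(TRUE, FALSE, TRUE, FALSE, FALSE), "TN")
  # an isolated target is sorted
  expect_equal(classifyScenario(FALSE, TRUE, FALSE, FALSE, FALSE), "TP")
})

test_that("all 32 scenarios match the brute-force displacement oracle", {
  g <- expand.grid(prev = c(TRUE, FALSE), self = c(TRUE, FALSE),
                   nxt = c(TRUE, FALSE), gp = c(TRUE, FALSE),
                   gn = c(TRUE, FALSE))
  tau <- 1.5e-3
  for (variant in c("alternating", "self-priority")) {
    for (i in seq_len(32)) {
      lab <- c(g$prev[i], g$self[i], g$nxt[i])
      gaps <- c(if (g$gp[i]) tau / 2 else 2 * tau,
                if (g$gn[i]) tau / 2 else 2 * tau)
      times <- c(0, gaps[1], gaps[1] + gaps[2])
      dest <- bruteDestinations(times, lab, tau, variant)[2]
      want <- if (lab[2]) {
        if (dest == "collection") "TP" else "FN"
      } else {
        if (dest == "collection") "FP" else "TN"
      }
      got <- classifyScenario(g$prev[i], g$self[i], g$nxt[i], g$gp[i],
                              g$gn[i], tau, variant)
      expect_equal(got, want,
                   info = sprintf("scenario %d variant %s", i, variant))
    }
  }
})

test_that("the rule variants differ exactly on in-window preceded targets", {
  # target preceded by an in-window actuation: alternating rules cancel the
  # pair (FN); self-priority lets the particle's own push win (TP)
  expect_equal(classifyScenario(TRUE, TRUE, FALSE, TRUE, FALSE,
                                variant = "alternating"), "FN")
  expect_equal(classifyScenario(TRUE, TRUE, FALSE, TRUE, FALSE,
                                variant = "self-priority"), "TP")
})

test_that("enumerateScenarios spans the 2^5 sample space", {
  tab <- enumerateScenarios(50, 1.5e-3, 0.6)
  sc <- scenarios(tab)
  expect_equal(nrow(sc), 32)
  expect_equal(sum(sc$probability), 1, tolerance = 1e-12)
  # all five-boolean combinations appear exactly once
  key <- with(sc, paste(prev_is_target, self_is_target, next_is_target,
                        gap_prev_short, gap_next_short))
  expect_equal(anyDuplicated(key), 0L)

  # probabilities sum to 1 over the whole parameter grid
  for (lam in c(1, 10, 50, 100, 200))
    for (tu in c(0.5e-3, 1.5e-3, 3e-3))
      for (r in c(0.1, 0.6, 0.9))
        expect_equal(sum(scenarios(enumerateScenarios(lam, tu, r))$probability),
                     1, tolerance = 1e-12)

  # no false positives exist at r = 1
  full <- scenarios(enumerateScenarios(100, 1.5e-3, 1))
  expect_equal(sum(full$probability[full$outcome == "FP"]), 0)
})

test_that("purityAnalytic has the right limits and monotonicity", {
  expect_equal(purityAnalytic(1e-9, 1.5e-3, 0.3), 1, tolerance = 1e-6)
  expect_equal(purityAnalytic(100, 1.5e-3, 1), 1)
  expect_error(purityAnalytic(50, 1.5e-3, 0), "undefined")

  grid <- expand.grid(lam = c(1, 10, 50, 100, 200),
                      tu = c(0.5e-3, 1.5e-3, 3e-3),
                      r = c(0.1, 0.6, 0.9))
  grid$purity <- mapply(purityAnalytic, grid$lam, grid$tu, grid$r)
  expect_true(all(grid$purity >= 0 & grid$purity <= 1))
  # non-increasing in lambda at fixed (tau, r) and in tau at fixed (lambda, r)
  for (tu in unique(grid$tu)) for (r in unique(grid$r)) {
    p <- grid$purity[grid$tu == tu & grid$r == r]
    expect_true(all(diff(p) <= 1e-12))
  }
  for (lam in unique(grid$lam)) for (r in unique(grid$r)) {
    p <- grid$purity[grid$lam == lam & grid$r == r]
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("simulateSorting matches the brute-force engine on a stream", {
  set.seed(40)
  tr <- simulateArrivals(80, 0.6, nEvents = 2000)
  cfg <- sortTimingConfig(rate = 80)
  for (variant in c("alternating", "self-priority")) {
    cfgV <- sortTimingConfig(rate = 80, variant = variant)
    run <- simulateSorting(tr, cfgV)
    ev <- eventTable(run)
    brute <- bruteDestinations(ev$time_s, ev$is_target, tau(cfgV), variant)
    expect_identical(ev$destination, brute)
  }
  # an isolated target is actuated and collected
  iso <- simulateSorting(0.5, cfg, decisions = TRUE, labels = TRUE)
  expect_equal(eventTable(iso)$outcome, "TP")
  expect_equal(eventTable(iso)$destination, "collection")

  # the scenario-7 triple realized with gaps (tau/2, 2 tau)
  tu <- tau(cfg)
  run7 <- simulateSorting(c(0, tu / 2, tu / 2 + 2 * tu), cfg,
                          decisions = c(TRUE, FALSE, TRUE),
                          labels = c(TRUE, FALSE, TRUE))
  expect_equal(eventTable(run7)$destination[2], "collection")
  expect_equal(eventTable(run7)$outcome[2], "FP")

  expect_error(simulateSorting(c(1, 0.5), cfg, decisions = c(TRUE, TRUE)),
               "sorted")
})

test_that("sort runs conserve events and partition destinations", {
  set.seed(41)
  tr <- simulateArrivals(120, 0.4, nEvents = 5000)
  run <- simulateSorting(tr, sortTimingConfig(rate = 120))
  ev <- eventTable(run)
  cnt <- evaluateRun(run)
  expect_equal(cnt$TP + cnt$FP + cnt$TN + cnt$FN, nrow(ev))
  expect_equal(sum(ev$destination == "collection") +
                 sum(ev$destination == "waste"), nrow(ev))
})

test_that("Monte-Carlo purity agrees with the analytic model at low duty", {
  set.seed(42)
  for (lam in c(10, 50, 85.6)) {
    tu <- 1.5e-3
    tr <- simulateArrivals(lam, 0.6, nEvents = 1e5)
    run <- simulateSorting(tr, sortTimingConfig(rate = lam))
    m <- evaluateRun(run)
    pA <- purityAnalytic(lam, tu, 0.6)
    nColl <- m$TP + m$FP
    se <- sqrt(pA * (1 - pA) / nColl)
    expect_lt(abs(m$TP / nColl - pA), 3 * se + intervalProb(lam, tu)^2)
  }
})

test_that("faster flow gives pointwise higher purity at fixed throughput", {
  lams <- c(1, 5, 20, 50, 100, 200)
  cur <- throughputPurityCurve(lams, r = 0.6,
                               flowSpeeds = c(0.02, 0.04, 0.08))
  wide <- reshape(cur[, c("flow_speed", "lambda", "purity")],
                  idvar = "lambda", timevar = "flow_speed",
                  direction = "wide")
  expect_true(all(wide$purity.0.04 >= wide$purity.0.02 - 1e-12))
  expect_true(all(wide$purity.0.08 >= wide$purity.0.04 - 1e-12))
})

test_that("eventRate implements the 50-event sliding window", {
  # constant 100 events/s spacing: every e_i is 100 (up to the floating
  # representation of the 10 ms spacing)
  er <- eventRate(seq(0, by = 0.01, length.out = 200))
  expect_equal(eventRates(er), rep(100, 150), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(nominalThroughput(er), 100)

  # unit case: times 0..100 s at 1 event/s
  er1 <- eventRate(0:100)
  expect_true(all(eventRates(er1) == 1))
  expect_equal(er1@index, 51:101)

  # Poisson stream: the modal rate lands within 10% of lambda
  set.seed(43)
  tr <- simulateArrivals(50, 0.5, nEvents = 1e4)
  erP <- eventRate(eventTable(tr)$time_s)
  expect_lt(abs(nominalThroughput(erP) - 50) / 50, 0.10)

  expect_error(eventRate(1:50), "51")
  expect_error(eventRate(c(seq_len(60), 60)), "increasing")
})

test_that("purityYield implements the count definitions", {
  expect_equal(purityYield(100, 0, 0), list(purity = 1, yield = 1))
  expect_equal(purityYield(9, 1, 1), list(purity = 0.9, yield = 0.9))
  expect_equal(purityYield(0, 5, 10), list(purity = 0, yield = 0))
  # empty collection: purity undefined, flagged as NA rather than 0
  expect_true(is.na(purityYield(0, 0, 10)$purity))
  expect_error(purityYield(-1, 0, 0), "non-negative")
})
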