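# Spectral basis construction and pseudo-inverse unmixing.

test_that("buildBasis samples constituent spectra at selected wavenumbers", {
  # two separated Gaussian peaks sampled at their peak positions
  w <- seq(2850, 3050, by = 1)
  spectra <- data.frame(wavenumber_cm1 = w,
                        A = exp(-((w - 2900) / 10)^2),
                        B = exp(-((w - 3000) / 10)^2))
  b <- buildBasis(spectra, c(2900, 3000))
  R <- responses(b)
  expect_equal(dim(R), c(2L, 2L))
  expect_equal(diag(R), c(1, 1), tolerance = 1e-12)
  expect_true(all(diag(R) > R[row(R) != col(R)]))

  # one constituent, one wavenumber, unit value -> 1x1 [[1]]
  one <- data.frame(wavenumber_cm1 = c(2890, 2900, 2910), A = c(0, 1, 0))
  expect_equal(unname(responses(buildBasis(one, 2900))),
               matrix(1, 1, 1))

  # PS/PMMA-like toy spectra at the four acquisition wavenumbers: oracle is
  # a direct linear interpolation of the same table
  spec <- referenceSpectra()
  b4 <- buildBasis(spec, c(2899, 2954, 3006, 3034))
  expect_equal(dim(responses(b4)), c(4L, 2L))
  manual <- sapply(c("PS", "PMMA"), function(nm)
    approx(spec$wavenumber_cm1, spec[[nm]],
           xout = c(2899, 2954, 3006, 3034))$y)
  expect_equal(unname(responses(b4)), unname(manual), tolerance = 1e-12)
  sv <- svd(responses(b4))$d
  expect_true(is.finite(sv[1] / sv[2]))
})

test_that("buildBasis rejects invalid inputs", {
  spec <- referenceSpectra()
  expect_error(buildBasis(spec, c(2899, 5000)), "range")
  expect_error(buildBasis(spec, 2899), "as many")
  # duplicated sampling points give identical rows -> rank deficient
  dup <- data.frame(wavenumber_cm1 = c(2800, 3000),
                    A = c(1, 1), B = c(2, 2))
  expect_error(buildBasis(dup, c(2850, 2950)), "rank")
})

test_that("unmix solves the linear model", {
  b <- identityBasis2()
  expect_equal(unmix(c(3, 5), b), c(A = 3, B = 5))
  expect_equal(unmix(c(0, 0), b), c(A = 0, B = 0))

  # random 4x2 basis: exact recovery against a normal-equations oracle
  basis <- randomFullRankBasis(4, 2, seed = 11)
  cTrue <- c(2, 7)
  d <- drop(responses(basis) %*% cTrue)
  cHat <- unmix(d, basis)
  expect_lt(max(abs(cHat - cTrue)) / max(abs(cTrue)), 1e-9)
  R <- responses(basis)
  oracle <- solve(t(R) %*% R, t(R) %*% d)
  expect_equal(unname(cHat), unname(drop(oracle)), tolerance = 1e-9)

  expect_error(unmix(c(1, 2, 3), b), "length")
  expect_error(unmix(c(1, NA), b), "finite")
})

test_that("exact recovery and linearity hold over random bases", {
  set.seed(42)
  for (nc in 2:6) {
    for (k in seq_len(3)) {
      nk <- sample(seq_len(nc), 1)
      basis <- randomFullRankBasis(nc, nk)
      cTrue <- runif(nk, -2, 5)
      d <- drop(responses(basis) %*% cTrue)
      expect_lt(max(abs(unmix(d, basis) - cTrue)),
                1e-9 * max(1, max(abs(cTrue))))
      # linearity
      d1 <- runif(nc); d2 <- runif(nc); a <- 2.5; bb <- -1.25
      lhs <- unmix(a * d1 + bb * d2, basis)
      rhs <- a * unmix(d1, basis) + bb * unmix(d2, basis)
      expect_lt(max(abs(lhs - rhs)), 1e-9)
    }
  }
})

test_that("unmixImage applies unmix per pixel and commutes with averaging", {
  basis <- randomFullRankBasis(4, 2, seed = 7)
  R <- responses(basis)
  # constant field: every pixel responses %*% (1, 1)
  d0 <- drop(R %*% c(1, 1))
  img <- array(rep(d0, each = 6 * 5), c(6, 5, 4))
  out <- unmixImage(img, basis)
  expect_equal(dim(out), c(6L, 5L, 2L))
  expect_true(all(abs(out - 1) < 1e-9))

  # single-pixel image reduces to unmix
  px <- runif(4)
  one <- array(px, c(1, 1, 4))
  expect_equal(unname(drop(unmixImage(one, basis))),
               unname(unmix(px, basis)), tolerance = 1e-12)

  # commutation with the spatial mean
  set.seed(5)
  img <- array(runif(8 * 9 * 4), c(8, 9, 4))
  dec <- unmixImage(img, basis)
  meanThenUnmix <- unmix(apply(img, 3, mean), basis)
  unmixThenMean <- apply(dec, 3, mean)
  expect_equal(unname(unmixThenMean), unname(meanThenUnmix),
               tolerance = 1e-9)
})

test_that("basis and spectra round-trip through disk formats", {
  b <- defaultBasis()
  tf <- tempfile(fileext = ".json")
  writeBasis(b, tf)
  b2 <- readBasis(tf)
  expect_equal(responses(b2), responses(b), tolerance = 1e-12)
  expect_equal(wavenumbers(b2), wavenumbers(b))
  expect_equal(constituentNames(b2), constituentNames(b))

  spec <- referenceSpectra()
  cf <- tempfile(fileext = ".csv")
  writeSpectra(spec, cf)
  expect_equal(readSpectra(cf), spec, tolerance = 1e-12)
})
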