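test_that("the Hill curve model evaluates its defining points", {
  expect_equal(curveModel(10, 1000, 600, ec50 = 10, slope = 1), 800)
  expect_equal(curveModel(0, 1000, 600, ec50 = 10, slope = 2), 1000)
  expect_equal(curveModel(1e15, 1000, 600, ec50 = 10, slope = 1), 600,
               tolerance = 1e-9)
  ## hand-evaluated: 1000 - 400 / (1 + 10/30)
  expect_equal(curveModel(30, 1000, 600, ec50 = 10, slope = 1), 700)
  expect_error(curveModel(10, 1000, 600, ec50 = -1, slope = 1), "ec50")
  expect_error(curveModel(10, 1000, 600, ec50 = 10, slope = 0), "slope")
  expect_error(curveModel(-3, 1000, 600, ec50 = 10, slope = 1),
               "non-negative")
})

test_that("curve model is monotone non-increasing for quench parameters", {
  cs <- c(0, 10^seq(-2, 4, length.out = 50))
  set.seed(1)
  for (i in 1:20) {
    ec <- 10^runif(1, -1, 3); sl <- runif(1, 0.2, 6)
    y <- curveModel(cs, 1000, runif(1, 0, 999), ec, sl)
    expect_true(all(diff(y) <= 1e-9))
    yr <- curveModel(cs, 600, 1000, ec, sl)  # swapped plateaus reverse it
    expect_true(all(diff(yr) >= -1e-9))
  }
})

test_that("noiseless traces are recovered to 1e-6 relative error", {
  set.seed(42)
  for (i in 1:20) {
    ec <- 10^runif(1, log10(0.3), log10(2000))
    sl <- runif(1, 0.5, 5)
    fmax <- runif(1, 500, 2000)
    fmin <- fmax * (1 - runif(1, 0.2, 0.9))
    y <- oracleHill(LADDER, fmax, fmin, ec, sl)
    f <- fitDoseResponse(LADDER, y)
    expect_true(f$converged)
    expect_lt(abs(f$EC50 - ec) / ec, 1e-6)
    expect_lt(abs(f$slope - sl) / sl, 1e-6)
    expect_lt(abs(f$F_max - fmax) / fmax, 1e-6)
    expect_lt(abs(f$F_min - fmin) / fmin, 1e-6)
    expect_equal(f$R2, 1)
  }
})

test_that("LM least squares is at least as good as its initialization and a
           coarse grid oracle", {
  set.seed(7)
  for (i in 1:10) {
    y <- oracleHill(LADDER, 1000, 550, 10^runif(1, 0, 2.5),
                    runif(1, 0.6, 3)) + rnorm(11, 0, 20)
    f <- fitDoseResponse(LADDER, y)
    pred <- curveModel(LADDER, f$F_max, f$F_min, f$EC50, f$slope)
    sseFit <- sum((y - pred)^2)
    ## initialization: fMax = max, fMin = min, slope 1, EC50 at half-crossing
    half <- (max(y) + min(y)) / 2
    ec0 <- LADDER[-1][which.min(abs(y[-1] - half))]
    sseInit <- sum((y - curveModel(LADDER, max(y), min(y), ec0, 1))^2)
    expect_lte(sseFit, sseInit + 1e-9)
    expect_lte(sseFit, gridOracleSSE(LADDER, y) + 1e-9)
  }
})

test_that("flat traces end up rejectable, not fatal", {
  y <- rep(800, 11)
  f <- fitDoseResponse(LADDER, y)
  if (isTRUE(f$converged)) {
    expect_true(is.na(f$dF) || abs(f$dF) < 1)
  }
  flags <- applyFilters(f)
  expect_false(flags$pass_all)
})

test_that("median EC50 of noisy wells recovers the population value", {
  w <- wellSpec("A1", populationSpec("a2", 49, nCells = 120L),
                noiseSdFrac = 0.02, seed = 11)
  fits <- fitTraces(generateTraces(w))
  expect_lt(abs(median(fits$EC50, na.rm = TRUE) - 49) / 49, 0.10)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fitDoseResponse(c(0, 1, 3), c(1, 2, 3)), "5")
  expect_error(fitDoseResponse(c(0, 1, 1, 3, 10), rep(1, 5)), "increasing")
  expect_error(fitDoseResponse(LADDER, LADDER[-1]), "length")
})

test_that("R2 equals an independent two-pass computation", {
  set.seed(3)
  y <- oracleHill(LADDER, 1000, 600, 10, 1) + rnorm(11, 0, 15)
  pred <- oracleHill(LADDER, 990, 610, 11, 1.1)
  expect_equal(rSquared(y, pred),
               1 - sum((y - pred)^2) / sum((y - mean(y))^2))
  expect_equal(rSquared(y, rep(mean(y), 11)), 0)
  expect_equal(rSquared(y, y), 1)
  expect_true(is.na(rSquared(rep(5, 11), rep(5, 11))))
})

test_that("dynamic range follows its definition and scaling invariance", {
  expect_equal(dynamicRange(600, 1000), 40)
  expect_equal(dynamicRange(1000, 1000), 0)
  expect_equal(dynamicRange(0, 1000), 100)
  expect_equal(dynamicRange(6e5, 1e6), dynamicRange(600, 1000))
  expect_error(dynamicRange(1, 0), "fMax")
})

test_that("normalization maps plateaus to 0/1 and is linear", {
  y <- oracleHill(LADDER, 1000, 600, 10, 1)
  z <- normalizeCurve(y, 600, 1000)
  expect_equal(z[1], 1)
  expect_equal(normalizeCurve(600, 600, 1000), 0)
  expect_equal(normalizeCurve(oracleHill(10, 1000, 600, 10, 1), 600, 1000),
               0.5)
  ## average of normalized exact-model traces equals the normalized model
  y2 <- oracleHill(LADDER, 2000, 1200, 10, 1)
  expect_equal((z + normalizeCurve(y2, 1200, 2000)) / 2, z)
  expect_error(normalizeCurve(y, 700, 700), "degenerate")
})
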