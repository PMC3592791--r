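acceptedFits <- function(ec50, well = "A1") {
  data.frame(cell_id = seq_along(ec50), well_id = well, EC50 = ec50,
             slope = 1.5, dF = 50, R2 = 0.99, converged = TRUE,
             pass_all = TRUE)
}

test_that("well summary reports median, SEM and ordered quantiles", {
  s <- wellSummary(acceptedFits(c(1, 10, 100)))
  expect_equal(s$ec50_median, 10)
  expect_equal(s$ec50_sem, sd(c(1, 10, 100)) / sqrt(3))
  expect_equal(s$n_accepted, 3L)
  expect_true(s$ec50_q05 <= s$ec50_q25 && s$ec50_q25 <= s$ec50_q75 &&
                s$ec50_q75 <= s$ec50_q95)
})

test_that("degenerate wells are flagged, not fatal", {
  s1 <- wellSummary(acceptedFits(42))
  expect_equal(s1$ec50_median, 42)
  expect_equal(s1$ec50_sem, 0)
  expect_true(s1$degenerate)
  f <- acceptedFits(c(5, 6))
  f$pass_all <- FALSE
  s0 <- wellSummary(f)
  expect_equal(s0$n_accepted, 0L)
  expect_true(is.na(s0$ec50_median))
  expect_true(s0$degenerate)
})

test_that("summaries are invariant under row permutation", {
  f <- acceptedFits(10^runif(50, 0, 3))
  s1 <- wellSummary(f)
  s2 <- wellSummary(f[sample(nrow(f)), ])
  expect_equal(s1, s2)
})

test_that("a synthetic well recovers its population median", {
  w <- wellSpec("C5", populationSpec("a1", 10.1, nCells = 150L),
                noiseSdFrac = 0.02, seed = 31)
  fl <- applyFilters(fitTraces(generateTraces(w)))
  s <- wellSummary(fl, "C5")
  expect_lt(abs(s$ec50_median - 10.1) / 10.1, 0.10)
  expect_gt(s$n_accepted, 100)
})

test_that("identical groups give t = 0 and p = 1", {
  r <- compareGroups(c(3, 5, 9), c(3, 5, 9))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_false(r$significant)
})

test_that("the t statistic matches the textbook formula on a 3-vs-3 example", {
  a <- c(9.1, 10.4, 11.2)
  b <- c(29.5, 31.0, 35.2)
  r <- compareGroups(a, b)
  expect_equal(r$t, oracleT(a, b), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_error(compareGroups(5, c(1, 2)), "at least 2")
})

test_that("well-separated populations test as significantly different", {
  w1 <- wellSpec("A1", populationSpec("lo", 32, nCells = 100L), seed = 41)
  w2 <- wellSpec("A2", populationSpec("hi", 190, nCells = 100L), seed = 42)
  f1 <- applyFilters(fitTraces(generateTraces(w1)))
  f2 <- applyFilters(fitTraces(generateTraces(w2)))
  r <- compareGroups(f1$EC50[f1$pass_all], f2$EC50[f2$pass_all])
  expect_true(r$significant)
  expect_lt(r$p, 1e-6)
})

test_that("SEM shrinks with the square root of the well size", {
  ns <- c(40L, 80L, 160L, 320L)
  sems <- vapply(ns, function(n) {
    w <- wellSpec("A1", populationSpec("p", 49, nCells = n), seed = 50L + n)
    wellSummary(applyFilters(fitTraces(generateTraces(w))))$ec50_sem
  }, numeric(1))
  slope <- coef(lm(log(sems) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.2)
})

test_that("plate maps arrange wells on the grid and keep annotations", {
  s <- data.frame(well_id = c("A1", "A2", "B1", "B2"),
                  ec50_median = c(10, 40, 12, 300))
  pm <- plateMap(s, annotation = data.frame(
    well_id = c("A1", "A2", "B1", "B2"),
    drug = c("none", "none", "none", "strychnine")))
  expect_equal(pm$matrix["A", "1"], 10)
  expect_equal(pm$matrix["B", "2"], 300)
  expect_equal(pm$long$drug[pm$long$well_id == "B2"], "strychnine")
  expect_error(plateMap(rbind(s, s[1, ])), "duplicate")
  ## missing well renders as NA
  pm2 <- plateMap(s[-2, ])
  expect_true(is.na(pm2$matrix["A", "2"]))
})

test_that("a drug-shifted well shows an elevated median over control", {
  ctl <- wellSpec("A1", populationSpec("a1", 9.8, nCells = 80L), seed = 61)
  shift <- wellSpec("A2", populationSpec("a1_strych", 346, nCells = 80L),
                    seed = 62)
  sCtl <- wellSummary(applyFilters(fitTraces(generateTraces(ctl))), "A1")
  sShift <- wellSummary(applyFilters(fitTraces(generateTraces(shift))), "A2")
  expect_gt(sShift$ec50_median, 5 * sCtl$ec50_median)
})
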