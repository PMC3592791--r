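## hand-enumerated 8-row fixture: rows 1-2 fail R2 only, 3-4 fail dF only,
## 5 fails slope only, 6 fails slope and EC50, 7 fails EC50 only, 8 passes
## everything
filterFixture <- function() {
  data.frame(
    cell_id = paste0("c", 1:8),
    R2 =    c(0.85, 0.89, 0.95, 0.99, 0.95, 0.99, 0.95, 0.99),
    dF =    c(40,   50,   15,   100.5, 60,  70,   30,   40),
    slope = c(1.2,  2.0,  1.0,  3.0,  0.4,  5.5,  2.0,  1.0),
    EC50 =  c(10,   100,  50,   20,   10,   3500, 0.2,  300),
    converged = TRUE)
}

test_that("per-criterion flags match hand enumeration on the fixture", {
  flags <- applyFilters(filterFixture())
  expect_equal(sum(flags$pass_r2), 6L)
  expect_equal(sum(flags$pass_dF), 6L)
  expect_equal(sum(flags$pass_slope), 6L)
  expect_equal(sum(flags$pass_ec50), 6L)
  expect_equal(sum(flags$pass_all), 1L)
  expect_equal(flags$cell_id[flags$pass_all], "c8")
  rep <- filterReport(flags)
  expect_equal(rep$n_total, 8L)
  expect_equal(rep$n_pass$combined, 1L)
  expect_equal(rep$pct_pass$combined, 12.5)
})

test_that("window endpoints are inclusive and 0.9 is the R2 boundary", {
  f <- data.frame(R2 = c(0.90, 0.89999), dF = c(20, 100), slope = c(0.5, 5),
                  EC50 = c(0.3, 3000), converged = TRUE)
  flags <- applyFilters(f)
  expect_true(flags$pass_all[1])   # all four at the closed boundary
  expect_false(flags$pass_r2[2])
  expect_false(flags$pass_all[2])
  expect_true(all(flags[2, c("pass_dF", "pass_slope", "pass_ec50")]))
})

test_that("the combined set is the intersection of per-criterion sets", {
  set.seed(99)
  n <- 1000
  fits <- data.frame(
    cell_id = seq_len(n),
    R2 = runif(n, 0.5, 1),
    dF = runif(n, 0, 120),
    slope = runif(n, 0.1, 8),
    EC50 = 10^runif(n, -2, 4.5),
    converged = runif(n) > 0.05)
  flags <- applyFilters(fits)
  inter <- flags$pass_r2 & flags$pass_dF & flags$pass_slope & flags$pass_ec50
  expect_identical(which(flags$pass_all), which(inter))
  expect_false(any(flags$pass_all[!fits$converged]))
  rep <- filterReport(flags)
  expect_lte(rep$n_pass$combined,
             min(unlist(rep$n_pass[c("r2", "dF", "slope", "ec50")])))
})

test_that("widening any window never decreases pass counts", {
  set.seed(5)
  n <- 400
  fits <- data.frame(R2 = runif(n, 0.5, 1), dF = runif(n, 0, 120),
                     slope = runif(n, 0.1, 8), EC50 = 10^runif(n, -2, 4.5),
                     converged = TRUE)
  base <- filterReport(applyFilters(fits))
  wide <- filterReport(applyFilters(fits, filterCriteria(
    r2Min = 0.8, dFWindow = c(10, 110), slopeWindow = c(0.2, 8),
    ec50Window = c(0.1, 10000))))
  for (k in names(base$n_pass))
    expect_gte(wide$n_pass[[k]], base$n_pass[[k]])
})

test_that("trivial windows pass every converged fit", {
  set.seed(6)
  fits <- data.frame(R2 = runif(50, -2, 1), dF = runif(50, -50, 200),
                     slope = runif(50, 0.01, 30), EC50 = 10^runif(50, -3, 6),
                     converged = rep(c(TRUE, FALSE), 25))
  flags <- applyFilters(fits, filterCriteria(
    r2Min = -Inf, dFWindow = c(-Inf, Inf), slopeWindow = c(-Inf, Inf),
    ec50Window = c(-Inf, Inf)))
  expect_identical(flags$pass_all, fits$converged)
})

test_that("empty input yields an empty result and NA percentages", {
  flags <- applyFilters(data.frame(R2 = numeric(), dF = numeric(),
                                   slope = numeric(), EC50 = numeric(),
                                   converged = logical()))
  expect_equal(nrow(flags), 0L)
  rep <- filterReport(flags)
  expect_equal(rep$n_total, 0L)
  expect_true(all(is.na(unlist(rep$pct_pass))))
})
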