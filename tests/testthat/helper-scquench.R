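## Shared fixtures and independent oracles for the test suite. Everything is
## generated in code; no stored data.

LADDER <- c(0, 0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000, 3000)

## quick single-population well
quickWell <- function(ec50 = 49, n = 30L, seed = 1L, noise = 0,
                      name = "pop", ...) {
  wellSpec("A1", populationSpec(name, ec50, nCells = n), seed = seed,
           noiseSdFrac = noise, ...)
}

## independent Hill evaluation (never calls package code)
oracleHill <- function(conc, fmax, fmin, ec50, slope) {
  ifelse(conc == 0, fmax, fmax + (fmin - fmax) / (1 + (ec50 / conc)^slope))
}

## Brute-force grid oracle: minimum SSE over a log10(EC50) x slope grid with
## the two plateaus solved in closed form (the model y = fmax(1-w) + fmin*w
## is linear in them for fixed EC50 and slope). Plateaus are constrained to
## the same physically meaningful box the fitter searches, [0, 2 max(y)];
## when the unconstrained optimum leaves the box, the best boundary solution
## of the 2-variable quadratic is used. Independent of the package fitting
## path.
gridOracleSSE <- function(conc, y, lec50 = seq(-2, 4, length.out = 121),
                          slopes = seq(0.1, 8, length.out = 80)) {
  up <- 2 * max(y)
  clampBox <- function(v) pmin(pmax(v, 0), up)
  g <- expand.grid(le = lec50, s = slopes)
  W <- matrix(0, nrow(g), length(conc))
  for (j in seq_along(conc))
    if (conc[j] > 0)
      W[, j] <- 1 / (1 + (10^g$le / conc[j])^g$s)
  Wc <- W - rowMeans(W)
  Sxx <- rowSums(Wc^2)
  yc <- y - mean(y)
  Syy <- sum(yc^2)
  Sxy <- as.numeric(Wc %*% yc)
  b <- ifelse(Sxx < 1e-12, 0, Sxy / Sxx)
  a <- mean(y) - b * rowMeans(W)        # a = fmax, a + b = fmin
  sse <- Syy - b^2 * Sxx
  bad <- which(a < 0 | a > up | a + b < 0 | a + b > up)
  for (i in bad) {
    w <- W[i, ]
    cand <- Inf
    for (fmin in c(0, up)) {           # fixed fmin edge, optimize fmax
      fmax <- clampBox(sum((y - fmin * w) * (1 - w)) / sum((1 - w)^2))
      cand <- min(cand, sum((y - fmax * (1 - w) - fmin * w)^2))
    }
    for (fmax in c(0, up)) {           # fixed fmax edge, optimize fmin
      fmin <- clampBox(sum((y - fmax * (1 - w)) * w) / sum(w^2))
      cand <- min(cand, sum((y - fmax * (1 - w) - fmin * w)^2))
    }
    sse[i] <- cand
  }
  min(sse)
}

## textbook pooled-variance two-sample t statistic (manual arithmetic oracle)
oracleT <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

## training table for phenotype tests: two log-normal EC50 clusters
phenoTraining <- function(medians = c(low = 32, high = 190), n = 100L,
                          logSd = 0.15, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(names(medians), function(cl) {
    data.frame(cell_id = paste0(cl, seq_len(n)),
               EC50 = 10^rnorm(n, log10(medians[[cl]]), logSd),
               slope = runif(n, 0.5, 4), label = cl)
  }))
}
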