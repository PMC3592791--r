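## Single-cell dose-response fitting. The model is the four-parameter Hill
## (logistic-in-log-concentration) curve for a fluorescence signal that is
## quenched by increasing agonist: fMax is the plateau at the lowest agonist
## concentration, fMin the plateau at the highest, ec50 the half-maximal
## activation concentration and slope the Hill coefficient nH.

#' Four-parameter Hill dose-response model
#'
#' \deqn{F(c) = F_{max} + \frac{F_{min} - F_{max}}{1 + (EC_{50}/c)^{slope}}}
#'
#' `F(0)` is defined as `fMax` (the mathematical limit), so the agonist-free
#' control frame can be included in a fit. With `fMin <= fMax` and
#' `slope > 0` the curve is monotone non-increasing in concentration, as
#' expected for a quenched fluorophore.
#'
#' @param conc agonist concentration(s) in µM; must be non-negative.
#' @param fMax fluorescence plateau at lowest agonist concentration.
#' @param fMin fluorescence plateau at highest agonist concentration.
#' @param ec50 half-maximal activation concentration (µM); must be positive.
#' @param slope Hill coefficient; must be positive.
#' @return fluorescence value(s).
#' @examples
#' curveModel(10, fMax = 1000, fMin = 600, ec50 = 10, slope = 1)  # midpoint
#' @export
curveModel <- function(conc, fMax, fMin, ec50, slope) {
  if (any(conc < 0)) stop("'conc' must be non-negative")
  if (ec50 <= 0) stop("'ec50' must be positive")
  if (slope <= 0) stop("'slope' must be positive")
  ifelse(conc == 0, fMax, fMax + (fMin - fMax) / (1 + (ec50 / conc)^slope))
}

#' Coefficient of determination of a dose-response fit
#'
#' `1 - SSE/SST` with the total sum of squares taken about the mean observed
#' fluorescence. Equals 1 for a perfect fit and can be negative for fits
#' worse than the constant mean. For a zero-variance trace `SST = 0` and the
#' statistic is undefined; `NA` is returned as a sentinel which the quality
#' filters treat as a failure.
#'
#' @param observed observed fluorescence values.
#' @param predicted model predictions at the same concentrations.
#' @return R^2, or `NA` if the observations have zero variance.
#' @export
rSquared <- function(observed, predicted) {
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / sst
}

#' Percent dynamic range of a dose-response
#'
#' \deqn{\Delta F = 100\,(F_{max} - F_{min})/F_{max}}
#'
#' The percent fluorescence change between the low- and high-agonist
#' plateaus; 0 for a flat trace, 100 for complete quenching. Invariant under
#' uniform scaling of the two plateaus.
#'
#' @param fMin,fMax fitted plateaus; `fMax` must be positive.
#' @return dynamic range in percent.
#' @examples
#' dynamicRange(600, 1000)  # 40
#' @export
dynamicRange <- function(fMin, fMax) {
  if (any(fMax <= 0)) stop("'fMax' must be positive")
  100 * (fMax - fMin) / fMax
}

#' Normalize a trace to its fitted plateaus
#'
#' Maps fluorescence to `(F - fMin) / (fMax - fMin)`, i.e. roughly \[0, 1\]
#' with 1 at the unquenched and 0 at the fully quenched plateau, for
#' overlaying and averaging curves across cells.
#'
#' @param fluor fluorescence values.
#' @param fMin,fMax fitted plateaus; must differ.
#' @return normalized values.
#' @export
normalizeCurve <- function(fluor, fMin, fMax) {
  if (fMax == fMin)
    stop("degenerate fit: plateaus coincide, cannot normalize")
  (fluor - fMin) / (fMax - fMin)
}

## internal parameterization: EC50 in log10 for conditioning
hillPred <- function(conc, fMax, fMin, lec50, slope) {
  ifelse(conc == 0, fMax,
         fMax + (fMin - fMax) / (1 + (10^lec50 / conc)^slope))
}

#' Fit one single-cell dose-response by Levenberg-Marquardt least squares
#'
#' Estimates the four Hill parameters by nonlinear least squares
#' (Levenberg-Marquardt, via [minpack.lm::nls.lm]). The primary start is
#' taken from the data — `fMax` from the maximum observed fluorescence,
#' `fMin` from the minimum, EC50 from the concentration whose observation
#' lies closest to the half-range, slope 1 — and is supplemented by a small
#' multi-start set over (EC50, slope), keeping the solution with the lowest
#' residual sum of squares; single-start LM can stall in a local minimum
#' when the true EC50 sits near the edge of the ladder. EC50 is optimized
#' in log10 space with bounds \[1e-3, 1e6\] µM; slope is bounded to
#' \[0.05, 20\] and the plateaus to \[0, 2 max(F)\], which keeps debris
#' traces from diverging. A failed optimization is recorded
#' (`converged = FALSE`, parameters `NA`), not raised.
#'
#' @param conc agonist concentrations (µM), non-negative, strictly
#'   increasing, at least 5 points.
#' @param fluor observed mean fluorescence, same length.
#' @param includeControl logical; include the agonist-free `c = 0` point in
#'   the least squares (default `TRUE`, model value `fMax`).
#' @param weights optional per-point weights (default unweighted).
#' @return a one-row `data.frame`: `F_max`, `F_min`, `EC50`, `slope`, `R2`,
#'   `dF`, `converged`.
#' @examples
#' conc <- c(0, 0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000, 3000)
#' y <- curveModel(conc, 1000, 600, ec50 = 10.1, slope = 1.2)
#' fitDoseResponse(conc, y)
#' @export
fitDoseResponse <- function(conc, fluor, includeControl = TRUE,
                            weights = NULL) {
  if (length(conc) != length(fluor))
    stop("'conc' and 'fluor' must have the same length")
  if (length(conc) < 5L)
    stop("at least 5 dose-response points are required")
  if (any(conc < 0) || any(diff(conc) <= 0))
    stop("'conc' must be non-negative and strictly increasing")
  keep <- if (includeControl) rep(TRUE, length(conc)) else conc > 0
  cc <- conc[keep]; ff <- fluor[keep]
  w <- if (is.null(weights)) rep(1, length(cc)) else weights[keep]

  fmax0 <- max(ff); fmin0 <- min(ff)
  half <- (fmax0 + fmin0) / 2
  pos <- cc > 0
  ec0 <- cc[pos][which.min(abs(ff[pos] - half))]
  upperF <- 2 * max(max(ff), 1e-6)
  lower <- c(0, 0, -3, 0.05)
  upper <- c(upperF, upperF, 6, 20)
  sw <- sqrt(w)
  resFun <- function(p) sw * (ff - hillPred(cc, p[1], p[2], p[3], p[4]))

  lspan <- log10(range(cc[pos]))
  starts <- c(list(c(fmax0, fmin0, log10(ec0), 1)),
              unlist(lapply(seq(lspan[1], lspan[2], length.out = 3),
                            function(le) list(c(fmax0, fmin0, le, 1),
                                              c(fmax0, fmin0, le, 3))),
                     recursive = FALSE))
  best <- NULL
  for (st in starts) {
    r <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resFun, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(r)) next
    sse <- sum(r$fvec^2)
    if (is.finite(sse) && (is.null(best) || sse < best$sse))
      best <- list(par = r$par, sse = sse)
  }

  if (is.null(best)) {
    return(data.frame(F_max = NA_real_, F_min = NA_real_, EC50 = NA_real_,
                      slope = NA_real_, R2 = NA_real_, dF = NA_real_,
                      converged = FALSE))
  }
  p <- c(fMax = best$par[1], fMin = best$par[2], lec50 = best$par[3],
         slope = best$par[4])
  pred <- hillPred(cc, p[["fMax"]], p[["fMin"]], p[["lec50"]], p[["slope"]])
  r2 <- rSquared(ff, pred)
  dF <- if (p[["fMax"]] > 0) dynamicRange(p[["fMin"]], p[["fMax"]])
        else NA_real_
  data.frame(F_max = p[["fMax"]], F_min = p[["fMin"]],
             EC50 = 10^p[["lec50"]], slope = p[["slope"]],
             R2 = r2, dF = dF, converged = TRUE)
}

#' Fit every trace of a well
#'
#' Applies [fitDoseResponse] to each row of a [WellTraces-class] object.
#'
#' @param traces a [WellTraces-class].
#' @param includeControl,weights passed to [fitDoseResponse].
#' @return a `data.frame` with one row per cell: `cell_id`, `well_id`, the
#'   fitted parameters and quality measures.
#' @examples
#' tr <- generateTraces(wellSpec("A1", populationSpec("alpha2", 49,
#'   nCells = 10L), seed = 2))
#' fitTraces(tr)
#' @export
fitTraces <- function(traces, includeControl = TRUE, weights = NULL) {
  stopifnot(is(traces, "WellTraces"))
  fl <- fluorescence(traces)
  conc <- concentrations(traces)
  rows <- lapply(seq_len(nrow(fl)), function(i)
    fitDoseResponse(conc, fl[i, ], includeControl = includeControl,
                    weights = weights))
  out <- do.call(rbind, rows) %||%
    data.frame(F_max = numeric(), F_min = numeric(), EC50 = numeric(),
               slope = numeric(), R2 = numeric(), dF = numeric(),
               converged = logical())
  rd <- SummarizedExperiment::rowData(traces)
  cbind(data.frame(cell_id = as.character(rd$cell_id),
                   well_id = rep(wellId(traces), nrow(out)),
                   stringsAsFactors = FALSE),
        out)
}
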