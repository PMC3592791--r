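## Quality filtering of fitted dose-responses. Segmented objects always
## include biologically irrelevant matter — dead cells, cells expressing the
## reporter but no channel, cells that detach during perfusion — whose fitted
## parameters fall outside the plausible windows. Four per-cell criteria
## (R^2, dynamic range, slope, EC50) are applied as closed intervals and
## combined by logical AND.

#' Apply the four acceptance criteria to fitted results
#'
#' Each criterion is a closed-interval test on one fitted quantity; the
#' combined flag is the AND of all four. Non-converged fits (or fits with
#' undefined quality values) fail every criterion.
#'
#' @param fits `data.frame` from [fitTraces] (columns `R2`, `dF`, `slope`,
#'   `EC50`, `converged`).
#' @param criteria a [FilterCriteria-class].
#' @return `fits` with added logical columns `pass_r2`, `pass_dF`,
#'   `pass_slope`, `pass_ec50`, `pass_all`.
#' @examples
#' f <- data.frame(R2 = c(0.95, 0.89), dF = 40, slope = 1.2, EC50 = 10,
#'                 converged = TRUE)
#' applyFilters(f)$pass_all
#' @export
applyFilters <- function(fits, criteria = filterCriteria()) {
  validObject(criteria)
  inWin <- function(v, w) !is.na(v) & v >= w[1] & v <= w[2]
  ok <- !is.na(fits$converged) & fits$converged
  fits$pass_r2 <- ok & !is.na(fits$R2) & fits$R2 >= criteria@r2Min
  fits$pass_dF <- ok & inWin(fits$dF, criteria@dFWindow)
  fits$pass_slope <- ok & inWin(fits$slope, criteria@slopeWindow)
  fits$pass_ec50 <- ok & inWin(fits$EC50, criteria@ec50Window)
  fits$pass_all <- fits$pass_r2 & fits$pass_dF & fits$pass_slope &
    fits$pass_ec50
  fits
}

#' Per-criterion and combined filtering statistics
#'
#' Counts and percentages of cells passing each criterion alone and all four
#' combined, relative to the total number of fitted objects.
#'
#' @param flags output of [applyFilters].
#' @return a list: `n_total`, `n_pass` (named counts per criterion plus
#'   `combined`), `pct_pass` (same, in percent).
#' @export
filterReport <- function(flags) {
  crit <- c(r2 = "pass_r2", dF = "pass_dF", slope = "pass_slope",
            ec50 = "pass_ec50", combined = "pass_all")
  n <- nrow(flags)
  counts <- vapply(crit, function(col) sum(flags[[col]]), integer(1))
  list(n_total = n,
       n_pass = as.list(counts),
       pct_pass = as.list(if (n > 0) 100 * counts / n
                          else stats::setNames(rep(NA_real_, length(crit)),
                                               names(crit))))
}
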