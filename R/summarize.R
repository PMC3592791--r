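## Well- and plate-level aggregation of accepted single-cell fits, and
## two-group significance testing. EC50 is summarized as median +/- SEM
## (per-cell EC50s are approximately log-normal, so the median is the robust
## location); box-plot quantiles (5/25/75/95%) support inter-well
## reproducibility displays.

#' Summarize accepted fits of one well
#'
#' @param fits filtered fit table ([applyFilters] output) of one well; rows
#'   with `pass_all` are the accepted cells.
#' @param wellIdent plate coordinate recorded in the summary (default: taken
#'   from the table's `well_id`).
#' @return a one-row `data.frame`: `well_id`, `n_total`, `n_accepted`,
#'   `n_rejected`, `ec50_median`, `ec50_sem`, `slope_median`, `dF_median`,
#'   `ec50_q05`, `ec50_q25`, `ec50_q75`, `ec50_q95`, `degenerate` (TRUE when
#'   no or a single accepted cell makes the statistics undefined or trivial).
#'   A well with zero accepted cells yields `NA` statistics, flagged, not an
#'   error.
#' @examples
#' f <- applyFilters(data.frame(well_id = "A1", R2 = 0.99, dF = 40,
#'   slope = c(1, 2, 1.5), EC50 = c(1, 10, 100), converged = TRUE))
#' wellSummary(f)$ec50_median
#' @export
wellSummary <- function(fits, wellIdent = NULL) {
  if (is.null(wellIdent))
    wellIdent <- if (nrow(fits) && !is.null(fits$well_id))
      as.character(fits$well_id[1]) else NA_character_
  acc <- fits[!is.na(fits$pass_all) & fits$pass_all, , drop = FALSE]
  n <- nrow(acc)
  if (n == 0L) {
    return(data.frame(well_id = wellIdent, n_total = nrow(fits),
                      n_accepted = 0L, n_rejected = nrow(fits),
                      ec50_median = NA_real_, ec50_sem = NA_real_,
                      slope_median = NA_real_, dF_median = NA_real_,
                      ec50_q05 = NA_real_, ec50_q25 = NA_real_,
                      ec50_q75 = NA_real_, ec50_q95 = NA_real_,
                      degenerate = TRUE))
  }
  q <- stats::quantile(acc$EC50, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
  data.frame(well_id = wellIdent, n_total = nrow(fits), n_accepted = n,
             n_rejected = nrow(fits) - n,
             ec50_median = stats::median(acc$EC50),
             ec50_sem = if (n > 1) stats::sd(acc$EC50) / sqrt(n) else 0,
             slope_median = stats::median(acc$slope),
             dF_median = stats::median(acc$dF),
             ec50_q05 = q[1], ec50_q25 = q[2], ec50_q75 = q[3],
             ec50_q95 = q[4],
             degenerate = n < 2L)
}

#' Two-group comparison of per-cell EC50 values
#'
#' Unpaired two-sample Student's t-test (equal variances by default; set
#' `welch = TRUE` for the Welch correction) on per-cell EC50 values, with
#' significance at p < 0.05. Since per-cell EC50s are log-normal, testing on
#' log10 values is available via `logScale = TRUE`.
#'
#' @param ec50A,ec50B numeric vectors of per-cell EC50s; each needs >= 2
#'   values.
#' @param welch use the Welch degrees-of-freedom correction.
#' @param logScale test log10-transformed values.
#' @param alpha significance level (default 0.05).
#' @return a list: `t`, `df`, `p`, `significant`.
#' @examples
#' compareGroups(c(9, 10, 11), c(90, 100, 110))
#' @export
compareGroups <- function(ec50A, ec50B, welch = FALSE, logScale = FALSE,
                          alpha = 0.05) {
  if (length(ec50A) < 2L || length(ec50B) < 2L)
    stop("both groups need at least 2 values")
  if (logScale) {
    ec50A <- log10(ec50A)
    ec50B <- log10(ec50B)
  }
  tt <- stats::t.test(ec50A, ec50B, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < alpha)
}

#' Assemble well summaries into a plate map
#'
#' Arranges per-well summary statistics on the plate grid for color-map
#' reporting (median EC50 per well by default). Wells absent from the
#' summaries render as `NA`.
#'
#' @param summaries `data.frame` of [wellSummary] rows (unique `well_id`).
#' @param value column of `summaries` to map (default `"ec50_median"`).
#' @param annotation optional `data.frame` with `well_id` plus annotation
#'   columns (population, drug, drug concentration), merged onto the long
#'   table.
#' @return a list: `matrix` (rows = plate rows, columns = plate columns) and
#'   `long` (tidy table with `well_id`, `row`, `column`, `value`, any
#'   annotations).
#' @examples
#' s <- data.frame(well_id = c("A1", "A2", "B1", "B2"),
#'                 ec50_median = c(10, 40, 12, 300))
#' plateMap(s)$matrix
#' @export
plateMap <- function(summaries, value = "ec50_median", annotation = NULL) {
  if (anyDuplicated(summaries$well_id))
    stop("duplicate well_id in summaries")
  rows <- sub("^([A-P]).*", "\\1", summaries$well_id)
  cols <- as.integer(sub("^[A-P]", "", summaries$well_id))
  if (any(is.na(cols))) stop("malformed well_id; expected e.g. 'A1'")
  rl <- sort(unique(rows))
  cl <- sort(unique(cols))
  m <- matrix(NA_real_, length(rl), length(cl), dimnames = list(rl, cl))
  m[cbind(match(rows, rl), match(cols, cl))] <- summaries[[value]]
  long <- data.frame(well_id = summaries$well_id, row = rows, column = cols,
                     value = summaries[[value]], stringsAsFactors = FALSE)
  if (!is.null(annotation))
    long <- merge(long, annotation, by = "well_id", all.x = TRUE,
                  sort = FALSE)
  list(matrix = m, long = long[order(long$row, long$column), , drop = FALSE])
}

#' Plot a plate color map
#'
#' Tile plot of a per-well statistic across the plate. By default cold
#' colors mark low and warm colors high EC50 values; `reverseScale` flips
#' the orientation.
#'
#' @param pm result of [plateMap].
#' @param reverseScale flip the color-scale direction.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plotPlateMap <- function(pm, reverseScale = FALSE,
                         title = "Median EC50 (uM)") {
  long <- pm$long
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$column),
                                     y = .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_y_discrete(limits = rev(sort(unique(long$row)))) +
    ggplot2::scale_fill_viridis_c(option = "plasma",
                                  direction = if (reverseScale) -1 else 1,
                                  trans = "log10", na.value = "grey85") +
    ggplot2::labs(x = "column", y = "row", fill = "EC50", title = title) +
    ggplot2::theme_minimal()
}

#' Box-plot of accepted per-cell EC50s across wells
#'
#' @param fits filtered fit table covering several wells (`well_id`,
#'   `EC50`, `pass_all`).
#' @return a ggplot object with boxes (25--75%) and whiskers (5--95%).
#' @export
plotWellBoxes <- function(fits) {
  acc <- fits[fits$pass_all, , drop = FALSE]
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$well_id, y = .data$EC50)) +
    ggplot2::stat_summary(
      fun.data = function(v) {
        q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95))
        data.frame(ymin = q[1], lower = q[2], middle = q[3], upper = q[4],
                   ymax = q[5])
      },
      geom = "boxplot") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "well", y = "EC50 (uM)") +
    ggplot2::theme_minimal()
}
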