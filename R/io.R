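## Interchange formats between stages: CSV with header for tables
## (human-diffable, language-portable), JSON for reports and models, YAML
## for scenario configuration, multi-page 16-bit TIFF plus a JSON
## concentration sidecar for image series. All writers round-trip to full
## precision.

#' Write / read per-cell trace tables
#'
#' The CSV holds one row per cell: `cell_id`, any per-cell metadata columns
#' (`well_id`, object geometry or generator ground truth), then one
#' `conc_<value>` column per ladder step with the mean fluorescence at that
#' agonist concentration. Reading restores a [WellTraces-class]; rows with
#' non-finite fluorescence are excluded with a warning naming them.
#'
#' @param traces a [WellTraces-class].
#' @param path CSV file path.
#' @return `writeTraceCsv`: `path`, invisibly. `readTraceCsv`: a
#'   [WellTraces-class].
#' @export
writeTraceCsv <- function(traces, path) {
  stopifnot(is(traces, "WellTraces"))
  rd <- as.data.frame(SummarizedExperiment::rowData(traces))
  if (is.null(rd$well_id)) rd$well_id <- wellId(traces)
  fl <- fluorescence(traces)
  colnames(fl) <- paste0("conc_", concentrations(traces))
  tab <- cbind(rd, as.data.frame(fl), row.names = NULL)
  data.table::fwrite(tab, path)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  if (!nrow(tab) || is.null(tab$cell_id))
    stop("malformed trace CSV (no 'cell_id' column): ", path)
  concCols <- grep("^conc_", colnames(tab), value = TRUE)
  if (length(concCols) < 5L)
    stop("malformed trace CSV (fewer than 5 'conc_' columns): ", path)
  conc <- as.numeric(sub("^conc_", "", concCols))
  fl <- as.matrix(tab[, concCols, drop = FALSE])
  bad <- !apply(fl, 1, function(v) all(is.finite(v)))
  if (any(bad)) {
    warning("excluding ", sum(bad), " row(s) with non-finite fluorescence: ",
            paste(utils::head(tab$cell_id[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
    tab <- tab[!bad, , drop = FALSE]
    fl <- fl[!bad, , drop = FALSE]
  }
  meta <- tab[, setdiff(colnames(tab), concCols), drop = FALSE]
  wid <- if (!is.null(meta$well_id) && nrow(meta)) meta$well_id[1] else "A1"
  wellTraces(fl, conc, wellId = wid, rowData = meta)
}

#' Write / read fit tables
#'
#' @param fits fit `data.frame` (from [fitTraces], optionally filtered by
#'   [applyFilters]).
#' @param path CSV file path.
#' @return `writeFitCsv`: `path`, invisibly. `readFitCsv`: the
#'   `data.frame`.
#' @export
writeFitCsv <- function(fits, path) {
  data.table::fwrite(fits, path)
  invisible(path)
}

#' @rdname writeFitCsv
#' @export
readFitCsv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write / read an image series as multi-page 16-bit TIFF plus sidecar
#'
#' The TIFF holds one 16-bit grayscale page per ladder step; the JSON
#' sidecar records the well id and per-page agonist concentration. On read,
#' the page count is validated against the sidecar.
#'
#' @param series an [ImageSeries-class].
#' @param path TIFF file path.
#' @param sidecar JSON sidecar path (default `<path>.json`).
#' @return `writeImageSeries`: `path`, invisibly. `readImageSeries`: an
#'   [ImageSeries-class].
#' @export
writeImageSeries <- function(series, path,
                             sidecar = paste0(path, ".json")) {
  stopifnot(is(series, "ImageSeries"))
  tiff::writeTIFF(lapply(series@frames, function(m) m / 65535),
                  path, bits.per.sample = 16L)
  jsonlite::write_json(list(well_id = series@wellId,
                            concentrations = series@concentrations),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeImageSeries
#' @export
readImageSeries <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$concentrations))
    stop(sprintf(
      "page/concentration mismatch: %d TIFF page(s) vs %d concentration(s)",
      length(pages), length(meta$concentrations)))
  frames <- lapply(pages, function(p) round(p * 65535))
  imageSeries(frames, meta$concentrations,
              wellId = meta$well_id %||% "A1")
}

## turn a YAML population entry into a PopulationSpec
popFromList <- function(name, p) {
  populationSpec(
    name = name,
    ec50Median = p$ec50_median,
    ec50LogSd = p$ec50_log_sd %||% 0.15,
    slopeRange = unlist(p$slope_range %||% c(0.5, 3)),
    dFRange = unlist(p$dF_range %||% c(25, 90)),
    fractionResponders = p$fraction_responders %||% 1,
    nCells = p$n_cells %||% 150L,
    baselineMean = p$baseline_mean %||% 10000,
    baselineCv = p$baseline_cv %||% 0.2,
    radiusRange = unlist(p$radius_range %||% c(4, 8)))
}

#' Read a scenario configuration
#'
#' A scenario YAML defines named populations (EC50 median and spread, slope
#' and dynamic-range ranges, responder fraction), the plate layout (which
#' populations fill which wells, with mixing fractions, debris, detachment
#' and noise settings), optional well annotations (population, drug, drug
#' concentration), the generation mode (`trace` or `image`) and an optional
#' `classify` block (training wells, test wells, folds). Per-well seeds are
#' derived from the global seed, which a caller may override.
#'
#' @param path YAML file.
#' @param seed optional override of the scenario's global seed.
#' @return a list: `seed`, `mode`, `wells` (named list of
#'   [WellSpec-class]), `annotation` (`data.frame` or `NULL`), `classify`
#'   (list or `NULL`).
#' @export
readScenario <- function(path, seed = NULL) {
  sc <- yaml::read_yaml(path)
  if (is.null(sc$wells) || !length(sc$wells))
    configError("wells", "must list at least one well")
  if (is.null(sc$populations))
    configError("populations", "must define at least one population")
  seed <- as.integer(seed %||% sc$seed %||% 1L)
  mode <- sc$mode %||% "trace"
  if (!mode %in% c("trace", "image"))
    configError("mode", "must be 'trace' or 'image'")
  pops <- lapply(names(sc$populations), function(nm)
    popFromList(nm, sc$populations[[nm]]))
  names(pops) <- names(sc$populations)
  wells <- lapply(sc$wells, function(w) {
    if (is.null(w$well)) configError("well", "id is required")
    pnames <- unlist(w$populations)
    unknown <- setdiff(pnames, names(pops))
    if (length(unknown))
      configError("populations",
                  paste("references undefined population(s):",
                        paste(unknown, collapse = ", ")))
    wellSpec(
      wellId = w$well,
      populations = pops[pnames],
      fractions = if (!is.null(w$fractions)) unlist(w$fractions) else NULL,
      nCells = w$n_cells,
      concentrations = unlist(w$concentrations %||% DEFAULT_LADDER),
      debrisCount = w$debris_count %||% 0L,
      detachProbability = w$detach_probability %||% 0,
      noiseSdFrac = w$noise_sd_frac %||% 0.02,
      backgroundFrac = w$background_frac %||% 0.05,
      fieldSize = unlist(w$field_size %||% c(696L, 520L)),
      seed = deriveSeed(seed, "well", w$well))
  })
  names(wells) <- vapply(wells, wellId, character(1))
  if (anyDuplicated(names(wells)))
    configError("wells", "well ids must be unique")
  annotation <- if (!is.null(sc$annotations)) {
    a <- do.call(rbind, lapply(sc$annotations, as.data.frame))
    names(a)[names(a) == "well"] <- "well_id"
    a
  }
  list(seed = seed, mode = mode, wells = wells, annotation = annotation,
       classify = sc$classify)
}
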