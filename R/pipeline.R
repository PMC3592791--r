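## Pipeline driver: simulate -> (segment) -> fit -> filter -> summarize ->
## classify over a scenario, with a manifest recording seeds, per-stage
## counts and file hashes so a rerun with the same configuration is
## bit-identical.

PIPELINE_STAGES <- c("simulate", "segment", "fit", "filter", "summarize",
                     "classify")

#' Run the full analysis pipeline on a scenario
#'
#' Executes the selected stages for every well of the scenario. In `trace`
#' mode the generator emits per-cell traces directly; in `image` mode it
#' renders TIFF series which are then segmented and measured. Fits, filter
#' flags and reports, well summaries and the plate matrix are written as
#' CSV/JSON under `outDir`; when the scenario has a `classify` block, a
#' decision tree is trained on the training wells (class label = annotated
#' population) and applied to the test wells. All randomness derives from
#' the single scenario seed via named sub-streams, so reruns with the same
#' configuration are bit-identical.
#'
#' @param scenario path to a scenario YAML, or the list from
#'   [readScenario].
#' @param outDir output directory (created if needed).
#' @param seed optional override of the scenario seed.
#' @param stages subset of `c("simulate", "segment", "fit", "filter",
#'   "summarize", "classify")`; later stages read the artifacts of earlier
#'   ones from `outDir` and fail with a dependency error if absent.
#' @return the manifest, invisibly (also written to
#'   `<outDir>/manifest.json`).
#' @export
runPipeline <- function(scenario, outDir, seed = NULL,
                        stages = PIPELINE_STAGES) {
  if (is.character(scenario)) scenario <- readScenario(scenario, seed = seed)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("traces", "truth", "fits", "filtered", "reports", "summary"))
    dir.create(file.path(outDir, d), showWarnings = FALSE)
  wells <- scenario$wells
  counts <- list()
  tracePath <- function(w) file.path(outDir, "traces", paste0(w, ".csv"))
  fitPath <- function(w) file.path(outDir, "fits", paste0(w, ".csv"))
  filtPath <- function(w) file.path(outDir, "filtered", paste0(w, ".csv"))
  needs <- function(path, stage) {
    if (!file.exists(path))
      stop(sprintf("stage '%s' needs missing upstream artifact: %s",
                   stage, path), call. = FALSE)
    path
  }

  if ("simulate" %in% stages) {
    if (scenario$mode == "image")
      dir.create(file.path(outDir, "images"), showWarnings = FALSE)
    for (w in names(wells)) {
      if (scenario$mode == "trace") {
        tr <- generateTraces(wells[[w]])
        writeTraceCsv(tr, tracePath(w))
        truth <- as.data.frame(SummarizedExperiment::rowData(tr))
      } else {
        out <- renderImageSeries(wells[[w]])
        writeImageSeries(out$series,
                         file.path(outDir, "images", paste0(w, ".tif")))
        truth <- out$truth
      }
      data.table::fwrite(truth, file.path(outDir, "truth",
                                          paste0(w, ".csv")))
    }
    counts$simulate <- vapply(wells, slot, integer(1), "nCells")
  }

  if ("segment" %in% stages && scenario$mode == "image") {
    for (w in names(wells)) {
      series <- readImageSeries(
        needs(file.path(outDir, "images", paste0(w, ".tif")), "segment"))
      seg <- segmentReference(frames(series)[[1]], segmentationParams())
      writeTraceCsv(measureSeries(seg, series), tracePath(w))
    }
  }

  if ("fit" %in% stages) {
    for (w in names(wells)) {
      tr <- readTraceCsv(needs(tracePath(w), "fit"))
      writeFitCsv(fitTraces(tr), fitPath(w))
    }
    counts$fit <- length(wells)
  }

  if ("filter" %in% stages) {
    for (w in names(wells)) {
      flags <- applyFilters(readFitCsv(needs(fitPath(w), "filter")))
      writeFitCsv(flags, filtPath(w))
      jsonlite::write_json(filterReport(flags),
                           file.path(outDir, "reports",
                                     paste0("filter_", w, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if ("summarize" %in% stages) {
    summaries <- do.call(rbind, lapply(names(wells), function(w)
      wellSummary(readFitCsv(needs(filtPath(w), "summarize")),
                  wellIdent = w)))
    data.table::fwrite(summaries,
                       file.path(outDir, "summary", "well_summary.csv"))
    pm <- plateMap(summaries, annotation = scenario$annotation)
    utils::write.csv(pm$matrix,
                     file.path(outDir, "summary", "plate_matrix.csv"))
    counts$summarize <- nrow(summaries)
  }

  if ("classify" %in% stages && !is.null(scenario$classify)) {
    cfg <- scenario$classify
    dir.create(file.path(outDir, "classify"), showWarnings = FALSE)
    lab <- function(w) {
      a <- scenario$annotation
      if (!is.null(a) && w %in% a$well_id && !is.null(a$population))
        a$population[match(w, a$well_id)]
      else vapply(wells[[w]]@populations, slot, character(1), "name")[1]
    }
    train <- do.call(rbind, lapply(unlist(cfg$train_wells), function(w) {
      fits <- readFitCsv(needs(filtPath(w), "classify"))
      fits <- fits[fits$pass_all, , drop = FALSE]
      cbind(fits, label = lab(w))
    }))
    model <- trainClassifier(train, folds = cfg$folds %||% 10L,
                             seed = deriveSeed(scenario$seed, "cv"))
    writePhenotypeModel(model, file.path(outDir, "classify", "model.json"))
    preds <- do.call(rbind, lapply(unlist(cfg$test_wells), function(w) {
      fits <- readFitCsv(needs(filtPath(w), "classify"))
      fits <- fits[fits$pass_all, , drop = FALSE]
      res <- classifyCells(model, fits)
      data.frame(cell_id = fits$cell_id, well_id = w,
                 predicted_class = res$labels)
    }))
    data.table::fwrite(preds,
                       file.path(outDir, "classify", "predictions.csv"))
    fr <- table(factor(preds$predicted_class, model@classes))
    jsonlite::write_json(
      list(cv_accuracy = as.list(model@cvAccuracy),
           confusion = model@confusion,
           fractions = as.list(as.numeric(fr) / max(nrow(preds), 1L)),
           n_classified = nrow(preds)),
      file.path(outDir, "classify", "report.json"),
      auto_unbox = TRUE, digits = NA)
    counts$classify <- nrow(preds)
  }

  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json" &
                   !grepl("\\.log$", files)]
  manifest <- list(
    package = "scQuench",
    version = as.character(utils::packageVersion("scQuench")),
    seed = scenario$seed,
    mode = scenario$mode,
    stages = stages,
    wells = names(wells),
    counts = counts,
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            sub(paste0("^", outDir, "/?"), "", files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
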