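#' @import methods
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Default 11-point agonist ladder (µM): agonist-free control followed by the
## first ten steps of the half-log dilution series used in iodide-quench
## screens of glycine receptors.
DEFAULT_LADDER <- c(0, 0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000, 3000)

#' PopulationSpec: parameters of one receptor-expressing cell population
#'
#' Describes the latent functional phenotype of a homogeneous cell population:
#' where its per-cell EC50 values sit (log-normal around `ec50Median` with
#' log10 spread `ec50LogSd`), how steep the Hill slopes are, how large the
#' fluorescence-quench dynamic range is, and what fraction of cells respond at
#' all (cells expressing the reporter but no functional channel are
#' non-responders).
#'
#' @slot name class label for the population (e.g. `"alpha1"`).
#' @slot ec50Median median per-cell EC50 in µM; must be positive.
#' @slot ec50LogSd standard deviation of per-cell log10(EC50).
#' @slot slopeRange length-2 numeric, uniform range of Hill slopes.
#' @slot dFRange length-2 numeric in \[0, 100\], uniform range of the percent
#'   dynamic range for responder cells.
#' @slot fractionResponders fraction of cells in \[0, 1\] that respond.
#' @slot nCells default number of cells drawn from this population.
#' @slot baselineMean mean baseline fluorescence (arbitrary 16-bit counts).
#' @slot baselineCv coefficient of variation of the per-cell baseline.
#' @slot radiusRange length-2 numeric, uniform range of cell radii in pixels.
#' @exportClass PopulationSpec
setClass("PopulationSpec",
  representation(
    name = "character",
    ec50Median = "numeric",
    ec50LogSd = "numeric",
    slopeRange = "numeric",
    dFRange = "numeric",
    fractionResponders = "numeric",
    nCells = "integer",
    baselineMean = "numeric",
    baselineCv = "numeric",
    radiusRange = "numeric"
  )
)

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!is.finite(object@ec50Median) || object@ec50Median <= 0)
    msg <- c(msg, "'ec50Median' must be > 0")
  if (!is.finite(object@ec50LogSd) || object@ec50LogSd < 0)
    msg <- c(msg, "'ec50LogSd' must be >= 0")
  if (length(object@slopeRange) != 2L || any(object@slopeRange <= 0) ||
      diff(object@slopeRange) < 0)
    msg <- c(msg, "'slopeRange' must be an increasing pair of positive values")
  if (length(object@dFRange) != 2L || any(object@dFRange < 0) ||
      any(object@dFRange > 100) || diff(object@dFRange) < 0)
    msg <- c(msg, "'dFRange' must be an increasing pair within [0, 100]")
  if (object@fractionResponders < 0 || object@fractionResponders > 1)
    msg <- c(msg, "'fractionResponders' must be in [0, 1]")
  if (object@nCells < 0L) msg <- c(msg, "'nCells' must be >= 0")
  if (object@baselineMean <= 0) msg <- c(msg, "'baselineMean' must be > 0")
  if (object@baselineCv < 0) msg <- c(msg, "'baselineCv' must be >= 0")
  if (length(object@radiusRange) != 2L || any(object@radiusRange <= 0) ||
      diff(object@radiusRange) < 0)
    msg <- c(msg, "'radiusRange' must be an increasing pair of positive values")
  if (length(msg)) msg else TRUE
})

#' Construct a PopulationSpec
#'
#' @param name population label.
#' @param ec50Median median per-cell EC50 (µM).
#' @param ec50LogSd spread of per-cell log10(EC50); default 0.15 reproduces
#'   the per-cell scatter seen in single-well EC50/slope dot plots.
#' @param slopeRange uniform range of Hill slopes.
#' @param dFRange uniform range of percent dynamic range for responders.
#' @param fractionResponders fraction of responding cells (emulating the
#'   20--60% co-transfection efficiency of reporter and channel).
#' @param nCells default population size.
#' @param baselineMean,baselineCv baseline fluorescence mean (counts) and CV.
#' @param radiusRange cell radius range in pixels at the 2x2-binned 10x scale.
#' @return a validated [PopulationSpec-class] object.
#' @examples
#' populationSpec("alpha1", ec50Median = 10.1, slopeRange = c(0.5, 1.9))
#' @export
populationSpec <- function(name, ec50Median, ec50LogSd = 0.15,
                           slopeRange = c(0.5, 3), dFRange = c(25, 90),
                           fractionResponders = 1, nCells = 150L,
                           baselineMean = 10000, baselineCv = 0.2,
                           radiusRange = c(4, 8)) {
  new("PopulationSpec", name = name, ec50Median = ec50Median,
      ec50LogSd = ec50LogSd, slopeRange = as.numeric(slopeRange),
      dFRange = as.numeric(dFRange),
      fractionResponders = fractionResponders, nCells = as.integer(nCells),
      baselineMean = baselineMean, baselineCv = baselineCv,
      radiusRange = as.numeric(radiusRange))
}

setMethod("show", "PopulationSpec", function(object) {
  cat("PopulationSpec '", object@name, "'\n", sep = "")
  cat("  EC50 median: ", object@ec50Median, " uM (log10 sd ",
      object@ec50LogSd, ")\n", sep = "")
  cat("  slope: U[", object@slopeRange[1], ", ", object@slopeRange[2],
      "]  dF: U[", object@dFRange[1], ", ", object@dFRange[2], "]%\n",
      sep = "")
  cat("  responders: ", 100 * object@fractionResponders, "%  nCells: ",
      object@nCells, "\n", sep = "")
})

#' WellSpec: simulation recipe for one well
#'
#' Combines one or more [PopulationSpec-class] populations (with mixing
#' fractions summing to 1), a concentration ladder (first entry must be the
#' agonist-free control), debris and detachment settings, measurement noise,
#' and a seed. This is the unit the synthetic generator consumes, either at
#' trace level ([generateTraces]) or at image level ([renderImageSeries]).
#'
#' @slot wellId plate coordinate, row letter + column number (e.g. "A1").
#' @slot populations list of [PopulationSpec-class].
#' @slot fractions numeric mixing fractions, same length, summing to 1.
#' @slot nCells total number of cells in the well.
#' @slot concentrations agonist ladder in µM; first entry 0.
#' @slot debrisCount number of non-cellular fluorescent objects to render.
#' @slot detachProbability per-cell probability of detaching mid-series.
#' @slot noiseSdFrac measurement noise sd as a fraction of cell baseline.
#' @slot backgroundFrac background level as a fraction of mean cell baseline.
#' @slot fieldSize image width and height in pixels.
#' @slot seed integer seed controlling all randomness for this well.
#' @exportClass WellSpec
setClass("WellSpec",
  representation(
    wellId = "character",
    populations = "list",
    fractions = "numeric",
    nCells = "integer",
    concentrations = "numeric",
    debrisCount = "integer",
    detachProbability = "numeric",
    noiseSdFrac = "numeric",
    backgroundFrac = "numeric",
    fieldSize = "integer",
    seed = "integer"
  )
)

setValidity("WellSpec", function(object) {
  msg <- character()
  if (!grepl("^[A-P][0-9]{1,2}$", object@wellId))
    msg <- c(msg, "'wellId' must be a plate coordinate like 'A1'")
  if (!length(object@populations) ||
      !all(vapply(object@populations, is, logical(1), "PopulationSpec")))
    msg <- c(msg, "'populations' must be a non-empty list of PopulationSpec")
  if (length(object@fractions) != length(object@populations))
    msg <- c(msg, "'fractions' must match 'populations' in length")
  else if (abs(sum(object@fractions) - 1) > 1e-8 || any(object@fractions < 0))
    msg <- c(msg, "'fractions' must be non-negative and sum to 1")
  cc <- object@concentrations
  if (length(cc) < 5L) msg <- c(msg, "at least 5 concentrations are required")
  else {
    if (cc[1] != 0) msg <- c(msg, "first concentration must be 0 (control)")
    if (any(diff(cc) <= 0))
      msg <- c(msg, "concentrations must be strictly increasing")
  }
  if (object@debrisCount < 0L) msg <- c(msg, "'debrisCount' must be >= 0")
  if (object@detachProbability < 0 || object@detachProbability > 1)
    msg <- c(msg, "'detachProbability' must be in [0, 1]")
  if (object@noiseSdFrac < 0) msg <- c(msg, "'noiseSdFrac' must be >= 0")
  if (object@backgroundFrac < 0)
    msg <- c(msg, "'backgroundFrac' must be >= 0")
  if (length(object@fieldSize) != 2L || any(object@fieldSize < 16L))
    msg <- c(msg, "'fieldSize' must be two dimensions >= 16 px")
  if (length(msg)) msg else TRUE
})

#' Construct a WellSpec
#'
#' @param wellId plate coordinate (row letter + column number).
#' @param populations a single [PopulationSpec-class] or a list of them.
#' @param fractions mixing fractions (default equal split); must sum to 1.
#' @param nCells total cells in the well; defaults to the summed `nCells` of
#'   the populations.
#' @param concentrations agonist ladder (µM), first entry 0. The default is
#'   the agonist-free control plus ten half-log steps 0.1--3000 µM.
#' @param debrisCount number of debris blobs rendered at image level.
#' @param detachProbability per-cell probability of abrupt detachment.
#' @param noiseSdFrac Gaussian noise sd as a fraction of each cell's baseline.
#' @param backgroundFrac camera/solution background as a fraction of the mean
#'   cell baseline (default 5%).
#' @param fieldSize image dimensions in pixels (default 696 x 520).
#' @param seed integer seed for this well.
#' @return a validated [WellSpec-class] object.
#' @examples
#' wellSpec("A1", populationSpec("alpha2", 49), seed = 7)
#' @export
wellSpec <- function(wellId, populations, fractions = NULL, nCells = NULL,
                     concentrations = DEFAULT_LADDER, debrisCount = 0L,
                     detachProbability = 0, noiseSdFrac = 0.02,
                     backgroundFrac = 0.05, fieldSize = c(696L, 520L),
                     seed = 1L) {
  if (is(populations, "PopulationSpec")) populations <- list(populations)
  if (is.null(fractions))
    fractions <- rep(1 / length(populations), length(populations))
  if (is.null(nCells))
    nCells <- sum(vapply(populations, slot, integer(1), "nCells"))
  new("WellSpec", wellId = wellId, populations = populations,
      fractions = as.numeric(fractions), nCells = as.integer(nCells),
      concentrations = as.numeric(concentrations),
      debrisCount = as.integer(debrisCount),
      detachProbability = detachProbability, noiseSdFrac = noiseSdFrac,
      backgroundFrac = backgroundFrac, fieldSize = as.integer(fieldSize),
      seed = as.integer(seed))
}

setMethod("show", "WellSpec", function(object) {
  cat("WellSpec ", object@wellId, ": ", object@nCells, " cells, ",
      length(object@populations), " population(s) [",
      paste(vapply(object@populations, slot, character(1), "name"),
            collapse = ", "),
      "], ", length(object@concentrations), "-point ladder, seed ",
      object@seed, "\n", sep = "")
})

#' ImageSeries: one well's frames with per-frame agonist concentration
#'
#' Ordered 16-bit grayscale frames of a single well, one per ladder step; the
#' first frame is the unquenched agonist-free control on which segmentation is
#' performed. Frames are stored as integer-valued matrices in camera counts.
#'
#' @slot frames list of numeric matrices, all the same dimension.
#' @slot concentrations per-frame agonist concentration (µM), first 0.
#' @slot wellId plate coordinate.
#' @exportClass ImageSeries
setClass("ImageSeries",
  representation(frames = "list", concentrations = "numeric",
                 wellId = "character")
)

setValidity("ImageSeries", function(object) {
  msg <- character()
  if (!length(object@frames) ||
      !all(vapply(object@frames, is.matrix, logical(1))))
    msg <- c(msg, "'frames' must be a non-empty list of matrices")
  else {
    dims <- vapply(object@frames, dim, integer(2))
    if (any(dims != dims[, 1]))
      msg <- c(msg, "all frames must share the same dimensions")
  }
  if (length(object@concentrations) != length(object@frames))
    msg <- c(msg, "one concentration per frame is required")
  else if (length(object@concentrations) &&
           object@concentrations[1] != 0)
    msg <- c(msg, "first frame must be the agonist-free control (c = 0)")
  if (length(msg)) msg else TRUE
})

#' @describeIn ImageSeries-class constructor.
#' @param frames list of numeric matrices (camera counts).
#' @param concentrations per-frame agonist concentrations (µM).
#' @param wellId plate coordinate.
#' @export
imageSeries <- function(frames, concentrations, wellId = "A1") {
  new("ImageSeries", frames = frames,
      concentrations = as.numeric(concentrations), wellId = wellId)
}

setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@frames[[1]])
  cat("ImageSeries ", object@wellId, ": ", length(object@frames),
      " frames of ", d[1], " x ", d[2], " px, agonist ",
      min(object@concentrations), "-", max(object@concentrations),
      " uM\n", sep = "")
})

#' SegmentationParams: controls for iterative threshold segmentation
#'
#' The segmenter sweeps an intensity threshold downward from a high starting
#' quantile of the control frame; at each level, connected components whose
#' area falls inside \[`minArea`, `maxArea`\] are accepted and masked out
#' before the threshold is lowered. The sweep stops at an intensity floor
#' estimated from the background or after `maxIterations` levels.
#'
#' @slot thresholdStart starting threshold as a quantile of frame intensity.
#' @slot thresholdStep intensity decrement per iteration (counts); `NA` means
#'   divide the start-to-floor range evenly over `maxIterations`.
#' @slot minArea,maxArea accepted object area bounds in pixels.
#' @slot maxIterations maximum number of threshold levels.
#' @slot cropFrac central crop retained for analysis (fraction of each
#'   dimension); objects whose centroid falls outside are dropped.
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(thresholdStart = "numeric", thresholdStep = "numeric",
                 minArea = "integer", maxArea = "integer",
                 maxIterations = "integer", cropFrac = "numeric")
)

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (object@thresholdStart <= 0 || object@thresholdStart > 1)
    msg <- c(msg, "'thresholdStart' must be a quantile in (0, 1]")
  if (!is.na(object@thresholdStep) && object@thresholdStep <= 0)
    msg <- c(msg, "'thresholdStep' must be > 0")
  if (object@minArea >= object@maxArea)
    msg <- c(msg, "'minArea' must be < 'maxArea'")
  if (object@minArea < 1L) msg <- c(msg, "'minArea' must be >= 1")
  if (object@maxIterations < 1L) msg <- c(msg, "'maxIterations' must be >= 1")
  if (object@cropFrac <= 0 || object@cropFrac > 1)
    msg <- c(msg, "'cropFrac' must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct SegmentationParams
#'
#' Defaults assume the 2x2-binned 10x-objective scale (696 x 520 field):
#' healthy adherent cells cover roughly 20--800 px.
#'
#' @param thresholdStart starting quantile (default 0.995).
#' @param thresholdStep intensity decrement in counts (default `NA`: the
#'   start-to-floor range is split evenly over `maxIterations` levels).
#' @param minArea,maxArea object area gates in pixels.
#' @param maxIterations maximum threshold levels (default 10).
#' @param cropFrac central field fraction evaluated (default 1 = whole frame;
#'   set to e.g. 0.8 to emulate analysing only cells near the well centre).
#' @return a validated [SegmentationParams-class] object.
#' @export
segmentationParams <- function(thresholdStart = 0.995, thresholdStep = NA_real_,
                               minArea = 20L, maxArea = 800L,
                               maxIterations = 10L, cropFrac = 1) {
  new("SegmentationParams", thresholdStart = thresholdStart,
      thresholdStep = as.numeric(thresholdStep), minArea = as.integer(minArea),
      maxArea = as.integer(maxArea), maxIterations = as.integer(maxIterations),
      cropFrac = cropFrac)
}

setMethod("show", "SegmentationParams", function(object) {
  cat("SegmentationParams: start q=", object@thresholdStart,
      ", step=", ifelse(is.na(object@thresholdStep), "auto",
                        object@thresholdStep),
      ", area [", object@minArea, ", ", object@maxArea, "] px, <=",
      object@maxIterations, " levels\n", sep = "")
})

#' WellTraces: per-cell dose-response traces of one well
#'
#' A [SummarizedExperiment-class] whose single assay `"fluor"` holds one row
#' per cell/object and one column per ladder step (mean fluorescence in
#' camera counts). `colData` carries the per-frame agonist concentration;
#' `rowData` carries cell metadata — generator ground truth for synthetic
#' wells, object geometry for segmented wells. Use [concentrations()] and
#' [fluorescence()] to access, and [wellId()] for the plate coordinate.
#'
#' @exportClass WellTraces
setClass("WellTraces", contains = "SummarizedExperiment")

setValidity("WellTraces", function(object) {
  msg <- character()
  if (!"fluor" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'fluor' is required")
  if (!"concentration" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'concentration' is required")
  else {
    cc <- SummarizedExperiment::colData(object)$concentration
    if (length(cc) && cc[1] != 0)
      msg <- c(msg, "first column must be the agonist-free control (c = 0)")
  }
  if (is.null(metadata(object)$wellId))
    msg <- c(msg, "metadata 'wellId' is required")
  if (length(msg)) msg else TRUE
})

#' Construct a WellTraces object
#'
#' @param fluor numeric matrix, cells x ladder steps (mean fluorescence).
#' @param concentrations agonist concentration per column (µM), first 0.
#' @param wellId plate coordinate.
#' @param rowData optional per-cell metadata (`data.frame` or `DataFrame`).
#' @return a [WellTraces-class] object.
#' @export
wellTraces <- function(fluor, concentrations, wellId = "A1", rowData = NULL) {
  fluor <- as.matrix(fluor)
  colnames(fluor) <- paste0("c", seq_len(ncol(fluor)))
  if (is.null(rowData))
    rowData <- DataFrame(cell_id = rownames(fluor) %||%
                           paste0("cell", seq_len(nrow(fluor))))
  rowData <- DataFrame(rowData)
  if (is.null(rowData$cell_id))
    rowData$cell_id <- paste0("cell", seq_len(nrow(fluor)))
  rownames(fluor) <- rowData$cell_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fluor = fluor),
    colData = DataFrame(concentration = as.numeric(concentrations),
                        frame = seq_along(concentrations)),
    rowData = rowData)
  metadata(se)$wellId <- wellId
  new("WellTraces", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "WellTraces", function(object) {
  cat("WellTraces ", metadata(object)$wellId, ": ", nrow(object),
      " cells x ", ncol(object), " ladder points (",
      paste(signif(SummarizedExperiment::colData(object)$concentration, 3),
            collapse = ", "), " uM)\n", sep = "")
})

#' FilterCriteria: quality-control windows for fitted dose-responses
#'
#' The four empirically motivated acceptance windows applied to every fit:
#' goodness of fit R^2 at least `r2Min` (curve must represent the data),
#' dynamic range within `dFWindow` percent (cell must co-express reporter and
#' channel), Hill slope within `slopeWindow` (physiologically plausible
#' steepness), EC50 within `ec50Window` µM (inside the span probed by the
#' ladder and drug shifts). All windows are closed intervals.
#'
#' @slot r2Min minimum R^2 (default 0.9).
#' @slot dFWindow percent dynamic-range window (default \[20, 100\]).
#' @slot slopeWindow Hill-slope window (default \[0.5, 5\]).
#' @slot ec50Window EC50 window in µM (default \[0.3, 3000\]).
#' @exportClass FilterCriteria
setClass("FilterCriteria",
  representation(r2Min = "numeric", dFWindow = "numeric",
                 slopeWindow = "numeric", ec50Window = "numeric")
)

setValidity("FilterCriteria", function(object) {
  msg <- character()
  for (nm in c("dFWindow", "slopeWindow", "ec50Window")) {
    w <- slot(object, nm)
    if (length(w) != 2L || diff(w) < 0)
      msg <- c(msg, sprintf("'%s' must be a non-empty interval", nm))
  }
  if (length(object@r2Min) != 1L || is.na(object@r2Min))
    msg <- c(msg, "'r2Min' must be a single number")
  if (length(msg)) msg else TRUE
})

#' Construct FilterCriteria
#'
#' @param r2Min minimum R^2.
#' @param dFWindow dynamic-range window in percent.
#' @param slopeWindow Hill-slope window.
#' @param ec50Window EC50 window (µM).
#' @return a validated [FilterCriteria-class] object.
#' @examples
#' filterCriteria()  # the standard four windows
#' @export
filterCriteria <- function(r2Min = 0.9, dFWindow = c(20, 100),
                           slopeWindow = c(0.5, 5),
                           ec50Window = c(0.3, 3000)) {
  new("FilterCriteria", r2Min = r2Min, dFWindow = as.numeric(dFWindow),
      slopeWindow = as.numeric(slopeWindow),
      ec50Window = as.numeric(ec50Window))
}

setMethod("show", "FilterCriteria", function(object) {
  cat("FilterCriteria: R2 >= ", object@r2Min,
      "; dF in [", object@dFWindow[1], ", ", object@dFWindow[2],
      "]%; slope in [", object@slopeWindow[1], ", ", object@slopeWindow[2],
      "]; EC50 in [", object@ec50Window[1], ", ", object@ec50Window[2],
      "] uM\n", sep = "")
})

#' PhenotypeModel: decision-tree classifier over functional parameters
#'
#' An axis-aligned decision tree trained on per-cell (log10 EC50, slope)
#' features from filter-accepted cells of pure populations, together with its
#' stratified k-fold cross-validation record (per-class accuracy and summed
#' confusion matrix) and the seed that fixed the fold assignment.
#'
#' @slot tree the fitted [rpart::rpart] object (refit on the full training set).
#' @slot features character vector of feature column names used for splits.
#' @slot classes class labels in training order.
#' @slot folds number of CV folds.
#' @slot seed fold-assignment seed.
#' @slot cvAccuracy named numeric, held-out accuracy per class.
#' @slot confusion confusion matrix (true x predicted) summed over folds.
#' @exportClass PhenotypeModel
setClass("PhenotypeModel",
  representation(tree = "ANY", features = "character", classes = "character",
                 folds = "integer", seed = "integer", cvAccuracy = "numeric",
                 confusion = "matrix")
)

setValidity("PhenotypeModel", function(object) {
  msg <- character()
  if (length(object@classes) < 2L)
    msg <- c(msg, "at least 2 classes are required")
  if (!inherits(object@tree, "rpart"))
    msg <- c(msg, "'tree' must be an rpart fit")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhenotypeModel", function(object) {
  cat("PhenotypeModel: ", length(object@classes), " classes (",
      paste(object@classes, collapse = ", "), "), features: ",
      paste(object@features, collapse = ", "), "\n", sep = "")
  cat("  ", object@folds, "-fold CV accuracy: ",
      paste(sprintf("%s %.1f%%", names(object@cvAccuracy),
                    100 * object@cvAccuracy), collapse = ", "),
      "\n", sep = "")
})
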