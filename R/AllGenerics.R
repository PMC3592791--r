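#' Accessors for scQuench containers
#'
#' `wellId()` returns the plate coordinate, `concentrations()` the agonist
#' ladder (µM), `frames()` the list of image frames, and `fluorescence()` the
#' cells x ladder matrix of mean fluorescence values.
#'
#' @param x an [ImageSeries-class], [WellTraces-class] or [WellSpec-class].
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @rdname accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("fluorescence", function(x) standardGeneric("fluorescence"))

#' @rdname accessors
setMethod("wellId", "ImageSeries", function(x) x@wellId)

#' @rdname accessors
setMethod("wellId", "WellSpec", function(x) x@wellId)

#' @rdname accessors
setMethod("wellId", "WellTraces",
          function(x) S4Vectors::metadata(x)$wellId)

#' @rdname accessors
setMethod("concentrations", "ImageSeries", function(x) x@concentrations)

#' @rdname accessors
setMethod("concentrations", "WellSpec", function(x) x@concentrations)

#' @rdname accessors
setMethod("concentrations", "WellTraces", function(x)
  SummarizedExperiment::colData(x)$concentration)

#' @rdname accessors
setMethod("frames", "ImageSeries", function(x) x@frames)

#' @rdname accessors
setMethod("fluorescence", "WellTraces", function(x)
  SummarizedExperiment::assay(x, "fluor"))
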