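## Synthetic-plate generator: ground-truth cell populations, per-cell
## dose-response traces, and rendered image series. Every downstream stage
## (segmentation, fitting, filtering, summarization, phenotyping) is tested
## against the ground truth this module emits.

#' Sample ground-truth cells from a population
#'
#' Draws `nCells` latent cells: per-cell log10(EC50) is normal around
#' log10(`ec50Median`) with sd `ec50LogSd` (EC50 itself log-normal, so the
#' population median equals `ec50Median`); Hill slope and percent dynamic
#' range are uniform within their ranges; a Bernoulli draw with
#' `fractionResponders` decides whether a cell responds at all
#' (non-responders keep their baseline fluorescence at every concentration
#' and have `true_dF = 0`). Baseline fluorescence is log-normal with the
#' configured mean and CV; the cell radius is uniform.
#'
#' @param spec a [PopulationSpec-class].
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @param n optional override of `spec@nCells`.
#' @return a `data.frame` with one row per cell and columns `cell_id`,
#'   `class_label`, `x`, `y` (NA until placed on an image), `radius`,
#'   `baseline_F`, `true_EC50`, `true_slope`, `true_dF`, `responder`,
#'   `detach_frame` (NA; assigned at well level).
#' @examples
#' head(samplePopulation(populationSpec("alpha1", 10.1), seed = 1))
#' @export
samplePopulation <- function(spec, seed = 1L, n = NULL) {
  validObject(spec)
  n <- as.integer(n %||% spec@nCells)
  if (n < 0L) configError("nCells", "must be >= 0")
  set.seed(as.integer(seed))
  responder <- stats::runif(n) < spec@fractionResponders
  ## log-normal EC50: median preserved under the log10-normal draw
  ec50 <- 10^stats::rnorm(n, log10(spec@ec50Median), spec@ec50LogSd)
  slope <- stats::runif(n, spec@slopeRange[1], spec@slopeRange[2])
  dF <- ifelse(responder, stats::runif(n, spec@dFRange[1], spec@dFRange[2]), 0)
  sdlog <- sqrt(log(1 + spec@baselineCv^2))
  baseline <- stats::rlnorm(n, log(spec@baselineMean) - sdlog^2 / 2, sdlog)
  radius <- stats::runif(n, spec@radiusRange[1], spec@radiusRange[2])
  data.frame(
    cell_id = sprintf("%s_%04d", spec@name, seq_len(n)),
    class_label = rep(spec@name, n),
    x = rep(NA_real_, n), y = rep(NA_real_, n),
    radius = radius, baseline_F = baseline,
    true_EC50 = ec50, true_slope = slope, true_dF = dF,
    responder = responder, detach_frame = rep(NA_integer_, n),
    stringsAsFactors = FALSE)
}

#' Ground-truth fluorescence of a cell at a given agonist concentration
#'
#' For responder cells the fluorescence is quenched sigmoidally from
#' `baseline_F` at zero agonist towards `baseline_F * (1 - true_dF/100)` at
#' saturation, following the same four-parameter Hill model the fitter uses
#' (see [curveModel]); non-responders return `baseline_F` at every
#' concentration.
#'
#' @param cell a single-row `data.frame` (or list) with `baseline_F`,
#'   `true_EC50`, `true_slope`, `true_dF`, `responder`.
#' @param conc agonist concentration(s), µM; must be non-negative.
#' @return fluorescence value(s), same length as `conc`.
#' @examples
#' cell <- samplePopulation(populationSpec("a", 10), seed = 1, n = 1)
#' trueResponse(cell, c(0, 10, 1e6))
#' @export
trueResponse <- function(cell, conc) {
  if (any(conc < 0)) stop("agonist concentration must be non-negative")
  if (!isTRUE(as.logical(cell$responder)) || cell$true_dF == 0)
    return(rep(as.numeric(cell$baseline_F), length(conc)))
  curveModel(conc,
             fMax = cell$baseline_F,
             fMin = cell$baseline_F * (1 - cell$true_dF / 100),
             ec50 = cell$true_EC50,
             slope = cell$true_slope)
}

## Draw the full ground-truth cell table for a well (shared between the
## trace-level and image-level generators so both see identical cells).
sampleWellCells <- function(well) {
  validObject(well)
  counts <- diff(c(0L, round(cumsum(well@fractions) * well@nCells)))
  cells <- do.call(rbind, lapply(seq_along(well@populations), function(i) {
    samplePopulation(well@populations[[i]],
                     seed = deriveSeed(well@seed, "cells", well@wellId, i),
                     n = counts[i])
  }))
  if (is.null(cells)) return(cells)
  cells$cell_id <- sprintf("%s_%s", well@wellId, cells$cell_id)
  ## abrupt detachment: affected cells drop to background from a uniformly
  ## drawn frame (>= 2; the control frame is always intact)
  nFrames <- length(well@concentrations)
  set.seed(deriveSeed(well@seed, "detach", well@wellId))
  det <- stats::runif(nrow(cells)) < well@detachProbability
  cells$detach_frame[det] <-
    as.integer(sample(2:nFrames, sum(det), replace = TRUE))
  rownames(cells) <- NULL
  cells
}

## Deterministic background level for a well (fraction of the mixing-weighted
## mean cell baseline) so trace- and image-level generation agree exactly.
wellBackground <- function(well) {
  means <- vapply(well@populations, slot, numeric(1), "baselineMean")
  well@backgroundFrac * sum(means * well@fractions)
}

#' Generate per-cell dose-response traces for a well
#'
#' Trace-level shortcut that bypasses image rendering: each ground-truth cell
#' contributes its [trueResponse] at every ladder concentration plus additive
#' Gaussian noise with sd `noiseSdFrac * baseline_F`. Cells with a
#' `detach_frame` have every frame from that index on replaced by the
#' background level (plus the same noise), emulating cells washed away during
#' perfusion. The returned [WellTraces-class] carries the complete ground
#' truth in its `rowData`.
#'
#' @param well a [WellSpec-class].
#' @return a [WellTraces-class]; `rowData` columns are those of
#'   [samplePopulation].
#' @examples
#' tr <- generateTraces(wellSpec("A1", populationSpec("alpha2", 49), seed = 3))
#' tr
#' @export
generateTraces <- function(well) {
  cells <- sampleWellCells(well)
  conc <- well@concentrations
  nF <- length(conc)
  bg <- wellBackground(well)
  clean <- t(vapply(seq_len(nrow(cells)),
                    function(i) trueResponse(cells[i, ], conc),
                    numeric(nF)))
  detached <- outer(ifelse(is.na(cells$detach_frame), nF + 1L,
                           cells$detach_frame),
                    seq_len(nF), `<=`)
  clean[detached] <- bg
  set.seed(deriveSeed(well@seed, "noise", well@wellId))
  noise <- matrix(stats::rnorm(length(clean), 0,
                               well@noiseSdFrac * cells$baseline_F),
                  nrow = nrow(clean))
  wellTraces(clean + noise, conc, wellId = well@wellId, rowData = cells)
}

## Pixel offsets of a solid disc of the given radius (dx, dy integer pairs).
discOffsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

## Rejection-sample non-overlapping centers for discs of the given radii.
placeDiscs <- function(radii, width, height, seed, margin = 2,
                       occupiedX = numeric(), occupiedY = numeric(),
                       occupiedR = numeric(), maxTries = 5000L) {
  set.seed(seed)
  x <- occupiedX; y <- occupiedY; r <- occupiedR
  outX <- outY <- numeric(length(radii))
  for (i in seq_along(radii)) {
    ri <- radii[i]
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      px <- stats::runif(1, ri + 1, width - ri)
      py <- stats::runif(1, ri + 1, height - ri)
      if (!length(x) || all((x - px)^2 + (y - py)^2 > (r + ri + margin)^2)) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement failed: too many objects for the field area",
           call. = FALSE)
    outX[i] <- px; outY[i] <- py
    x <- c(x, px); y <- c(y, py); r <- c(r, ri)
  }
  list(x = outX, y = outY)
}

## Irregular debris blob: pixel set grown by random accretion (Eden-like),
## confined to the placement radius so blobs never leak into neighbouring
## objects; intensity is drawn fresh per frame (non-sigmoidal by
## construction).
debrisPixels <- function(nPixels, radius, seed) {
  set.seed(seed)
  px <- matrix(c(0L, 0L), ncol = 2)
  tries <- 0L
  maxTries <- 60L * nPixels
  while (nrow(px) < nPixels && tries < maxTries) {
    tries <- tries + 1L
    from <- px[sample.int(nrow(px), 1), ]
    step <- from + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    if (sum(step^2) > radius^2) next
    if (!any(px[, 1] == step[1] & px[, 2] == step[2]))
      px <- rbind(px, step)
  }
  px
}

#' Render a synthetic image series for a well
#'
#' Draws the same ground-truth cells as [generateTraces] (identical
#' sub-stream), places them on the field by rejection sampling so no two
#' objects overlap, and renders one 16-bit frame per ladder step: each cell
#' is a solid disc whose mean pixel value equals its [trueResponse] at that
#' frame's concentration, on a constant background (5% of the mean cell
#' baseline by default) with additive Gaussian pixel noise. Debris objects —
#' emulating dead cells, reporter-only cells and other non-cellular
#' fluorescent matter — are rendered as small or large irregular blobs whose
#' intensity varies arbitrarily from frame to frame. Detaching cells vanish
#' to background from their `detach_frame` on. Pixel values are rounded and
#' clipped to the 16-bit range.
#'
#' @param well a [WellSpec-class].
#' @return a list with `series` (an [ImageSeries-class]) and `truth` (the
#'   ground-truth `data.frame`, including debris rows labelled `"debris"`,
#'   with placed `x`, `y` coordinates).
#' @examples
#' w <- wellSpec("B2", populationSpec("alpha1", 10.1, nCells = 20L),
#'               fieldSize = c(160L, 120L), seed = 5)
#' out <- renderImageSeries(w)
#' out$series
#' @export
renderImageSeries <- function(well) {
  cells <- sampleWellCells(well)
  conc <- well@concentrations
  nF <- length(conc)
  W <- well@fieldSize[1]; H <- well@fieldSize[2]
  bg <- wellBackground(well)

  ## debris geometry: half tiny fragments (below any plausible cell area),
  ## half large clumps (above it)
  nDeb <- well@debrisCount
  set.seed(deriveSeed(well@seed, "debris-geom", well@wellId))
  debSmall <- nDeb %/% 2 + nDeb %% 2
  debArea <- c(if (debSmall) sample(3:12, debSmall, replace = TRUE),
               if (nDeb - debSmall)
                 sample(900:1800, nDeb - debSmall, replace = TRUE))
  debRadius <- sqrt(debArea / pi) + 3

  ## place big objects first so rejection sampling converges on dense fields
  radii <- c(cells$radius, debRadius)
  ord <- order(radii, decreasing = TRUE)
  placed <- placeDiscs(radii[ord], W, H,
                       seed = deriveSeed(well@seed, "place", well@wellId))
  place <- list(x = numeric(length(radii)), y = numeric(length(radii)))
  place$x[ord] <- placed$x
  place$y[ord] <- placed$y
  cells$x <- place$x[seq_len(nrow(cells))]
  cells$y <- place$y[seq_len(nrow(cells))]

  ## precompute pixel linear indices per object
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  cellIdx <- lapply(seq_len(nrow(cells)), function(i) {
    off <- discOffsets(cells$radius[i])
    ix <- clamp(round(cells$x[i]) + off$dx, 1L, W)
    iy <- clamp(round(cells$y[i]) + off$dy, 1L, H)
    unique((ix - 1L) * H + iy)  # column-major linear index into H x W matrix
  })
  debIdx <- lapply(seq_len(nDeb), function(j) {
    px <- debrisPixels(debArea[j], radius = debRadius[j] - 1,
                       seed = deriveSeed(well@seed, "debris-px",
                                         well@wellId, j))
    cx <- round(place$x[nrow(cells) + j]); cy <- round(place$y[nrow(cells) + j])
    ix <- clamp(cx + px[, 1], 1L, W)
    iy <- clamp(cy + px[, 2], 1L, H)
    unique((ix - 1L) * H + iy)
  })

  set.seed(deriveSeed(well@seed, "debris-int", well@wellId))
  baseMean <- mean(vapply(well@populations, slot, numeric(1), "baselineMean"))
  debInt <- matrix(stats::runif(nDeb * nF, 0.3, 1.3) * baseMean,
                   nrow = max(nDeb, 1L))

  set.seed(deriveSeed(well@seed, "pixel-noise", well@wellId))
  framesOut <- vector("list", nF)
  for (k in seq_len(nF)) {
    fr <- matrix(bg, nrow = H, ncol = W)
    if (well@noiseSdFrac > 0)
      fr <- fr + stats::rnorm(H * W, 0, well@noiseSdFrac * bg)
    for (i in seq_len(nrow(cells))) {
      gone <- !is.na(cells$detach_frame[i]) && k >= cells$detach_frame[i]
      if (gone) next
      v <- trueResponse(cells[i, ], conc[k])
      idx <- cellIdx[[i]]
      nz <- if (well@noiseSdFrac > 0)
        stats::rnorm(length(idx), 0, well@noiseSdFrac * cells$baseline_F[i])
      else 0
      fr[idx] <- v + nz
    }
    for (j in seq_len(nDeb)) {
      idx <- debIdx[[j]]
      nz <- if (well@noiseSdFrac > 0)
        stats::rnorm(length(idx), 0, well@noiseSdFrac * debInt[j, k]) else 0
      fr[idx] <- debInt[j, k] + nz
    }
    framesOut[[k]] <- matrix(clamp(round(fr), 0, 65535), nrow = H)
  }

  truth <- cells
  if (nDeb > 0) {
    debTruth <- data.frame(
      cell_id = sprintf("%s_debris_%04d", well@wellId, seq_len(nDeb)),
      class_label = "debris",
      x = place$x[nrow(cells) + seq_len(nDeb)],
      y = place$y[nrow(cells) + seq_len(nDeb)],
      radius = debRadius, baseline_F = debInt[, 1],
      true_EC50 = NA_real_, true_slope = NA_real_, true_dF = 0,
      responder = FALSE, detach_frame = NA_integer_,
      stringsAsFactors = FALSE)
    truth <- rbind(truth, debTruth)
  }
  truth$well_id <- rep(well@wellId, nrow(truth))
  list(series = imageSeries(framesOut, conc, wellId = well@wellId),
       truth = truth)
}
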