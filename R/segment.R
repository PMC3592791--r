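## Cell identification on the unquenched control frame by an iterative size-
## and intensity-based thresholding sweep, and extraction of per-object mean
## fluorescence across every frame of the series. ROIs found on frame 1 are
## held fixed across frames: cells are stationary, the control frame is the
## brightest, and objects that vanish mid-series (detaching cells) are left
## to the downstream quality filters rather than tracked.

## 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
## touch diagonally are merged with a union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  H <- nrow(lab); W <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    dr <- shift[1]; dc <- shift[2]
    rows <- seq_len(H - dr)
    cols <- if (dc > 0) seq_len(W - dc) else seq.int(1 - dc, W)
    a <- lab[rows, cols, drop = FALSE]
    b <- lab[rows + dr, cols + dc, drop = FALSE]
    hit <- which(a > 0L & b > 0L & a != b)
    for (k in hit) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

## dilate a logical mask by one pixel in all 8 directions
dilate1 <- function(mask) {
  out <- mask
  H <- nrow(mask); W <- ncol(mask)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(H, H + dr)
    rt <- max(1, 1 - dr):min(H, H - dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    ct <- max(1, 1 - dc):min(W, W - dc)
    out[rt, ct] <- out[rt, ct] | mask[rs, cs]
  }
  out
}

#' Segment the control frame by iterative threshold lowering
#'
#' Starting from a high intensity quantile of the agonist-free control frame,
#' the threshold is lowered step by step; at each level, 8-connected
#' components of the above-threshold pixels whose area lies within
#' \[`minArea`, `maxArea`\] are accepted as objects and masked out (together
#' with a one-pixel guard ring, so later levels cannot grow rings around
#' them — an object found at a higher threshold wins any overlap). The sweep
#' stops at an intensity floor estimated from the background (median plus
#' five robust standard deviations) or after `maxIterations` levels.
#' Finally, an accepted object that turns out to be the bright core of an
#' over-sized structure — its 8-connected component at the floor threshold
#' exceeds `maxArea` — is rejected. An all-background frame yields an empty
#' result, not an error.
#'
#' @param frame0 numeric matrix, the control (c = 0) frame.
#' @param params a [SegmentationParams-class].
#' @return a list: `labels` (integer matrix, 0 = background) and `objects`
#'   (`data.frame` with `object_id`, `x`, `y` centroid, `area`).
#' @examples
#' w <- wellSpec("A1", populationSpec("alpha1", 10.1, nCells = 15L),
#'               fieldSize = c(200L, 160L), seed = 4)
#' seg <- segmentReference(frames(renderImageSeries(w)$series)[[1]],
#'                         segmentationParams())
#' nrow(seg$objects)
#' @export
segmentReference <- function(frame0, params = segmentationParams()) {
  stopifnot(is.matrix(frame0))
  validObject(params)
  H <- nrow(frame0); W <- ncol(frame0)
  start <- stats::quantile(frame0, params@thresholdStart, names = FALSE)
  ## floor strictly above the background: median + 5 robust sd, but never
  ## the median itself (noise-free frames have mad = 0)
  floorThr <- stats::median(frame0) + max(5 * stats::mad(frame0), 0.5)
  if (floorThr >= start) floorThr <- min(start, stats::median(frame0) + 0.5)
  thresholds <- if (is.na(params@thresholdStep)) {
    seq(start, floorThr, length.out = params@maxIterations)
  } else {
    head(seq(start, floorThr, by = -params@thresholdStep),
         params@maxIterations)
  }

  labels <- matrix(0L, H, W)
  blocked <- matrix(FALSE, H, W)  # accepted objects + guard ring
  nextId <- 0L
  rowIdx <- row(frame0)
  colIdx <- col(frame0)
  for (thr in thresholds) {
    mask <- frame0 >= thr & !blocked
    if (!any(mask)) next
    lab <- label8(mask)
    if (max(lab) == 0L) next
    areas <- tabulate(lab[lab > 0L])
    ok <- which(areas >= params@minArea & areas <= params@maxArea)
    if (!length(ok)) {
      ## still block over-sized components at this level? No: they may split
      ## into valid objects at a later (lower) level only if they grow, which
      ## cannot happen; leave them for the area gate each round.
      next
    }
    for (comp in ok) {
      sel <- lab == comp
      nextId <- nextId + 1L
      labels[sel] <- nextId
    }
    blocked <- blocked | dilate1(labels > 0L)
  }

  ## size consistency at the floor: an object accepted from the bright core
  ## of a larger structure (e.g. a big debris clump whose pixels straddle one
  ## threshold level because of noise) sits inside an over-sized connected
  ## component once the threshold reaches the floor; such objects are
  ## rejected.
  if (nextId > 0L) {
    floorLab <- label8(frame0 >= min(thresholds))
    floorArea <- tabulate(floorLab[floorLab > 0L])
    drop <- integer()
    homeComp <- rep(NA_integer_, nextId)
    for (id in seq_len(nextId)) {
      px <- which(labels == id)
      comp <- floorLab[px]
      comp <- comp[comp > 0L]
      if (!length(comp)) next
      homeComp[id] <- comp[1]
      if (max(floorArea[unique(comp)]) > params@maxArea)
        drop <- c(drop, id)
    }
    ## one object per physical structure: if several accepted objects share a
    ## floor component (a later fragment of an already-accepted cell), the
    ## first — highest-threshold — acceptance wins
    dupes <- which(!is.na(homeComp) & duplicated(homeComp))
    drop <- sort(unique(c(drop, dupes)))
    if (length(drop)) {
      labels[labels %in% drop] <- 0L
      keepIds <- setdiff(seq_len(nextId), drop)
      labels <- matrix(match(labels, c(0L, keepIds), nomatch = 1L) - 1L,
                       H, W)
      labels <- matrix(as.integer(labels), H, W)
      nextId <- length(keepIds)
    }
  }

  if (nextId == 0L) {
    return(list(labels = labels,
                objects = data.frame(object_id = integer(), x = numeric(),
                                     y = numeric(), area = integer())))
  }
  idx <- which(labels > 0L)
  lv <- labels[idx]
  area <- tabulate(lv, nbins = nextId)
  cx <- rowsum(colIdx[idx], lv)[, 1] / area  # x = column
  cy <- rowsum(rowIdx[idx], lv)[, 1] / area  # y = row
  objects <- data.frame(object_id = seq_len(nextId), x = cx, y = cy,
                        area = as.integer(area))

  ## optional central-field crop: drop objects whose centroid lies outside
  if (params@cropFrac < 1) {
    mx <- W * (1 - params@cropFrac) / 2
    my <- H * (1 - params@cropFrac) / 2
    keep <- objects$x >= mx & objects$x <= W - mx &
            objects$y >= my & objects$y <= H - my
    drop <- objects$object_id[!keep]
    labels[labels %in% drop] <- 0L
    objects <- objects[keep, , drop = FALSE]
    relab <- match(labels, c(0L, objects$object_id)) - 1L
    labels <- matrix(as.integer(relab), H, W)
    objects$object_id <- seq_len(nrow(objects))
    rownames(objects) <- NULL
  }
  list(labels = labels, objects = objects)
}

#' Measure mean object fluorescence on every frame
#'
#' For each segmented object the mean of all pixel values within its (fixed)
#' pixel set is computed on every frame of the series and paired with that
#' frame's agonist concentration, yielding one dose-response trace per
#' object.
#'
#' @param segmentation result of [segmentReference] (on the series' control
#'   frame).
#' @param series an [ImageSeries-class] with frames matching the label map's
#'   dimensions.
#' @return a [WellTraces-class]; `rowData` carries `cell_id` (object id),
#'   `x`, `y`, `area`.
#' @export
measureSeries <- function(segmentation, series) {
  stopifnot(is(series, "ImageSeries"))
  labels <- segmentation$labels
  objects <- segmentation$objects
  if (!all(dim(labels) == dim(series@frames[[1]])))
    stop("label map and frames disagree in shape")
  idx <- which(labels > 0L)
  lv <- labels[idx]
  n <- nrow(objects)
  fl <- matrix(NA_real_, nrow = n, ncol = length(series@frames))
  if (n > 0) {
    area <- tabulate(lv, nbins = n)
    for (k in seq_along(series@frames)) {
      fl[, k] <- rowsum(series@frames[[k]][idx], lv)[, 1] / area
    }
  }
  rd <- data.frame(cell_id = sprintf("%s_obj_%04d", series@wellId,
                                     objects$object_id),
                   x = objects$x, y = objects$y, area = objects$area,
                   stringsAsFactors = FALSE)
  wellTraces(fl, series@concentrations, wellId = series@wellId, rowData = rd)
}

#' Match detected objects to ground-truth cells
#'
#' Greedy nearest matching: a detection counts as a true positive if its
#' centroid lies within the radius of an unmatched ground-truth cell.
#' Intended for validating [segmentReference] against the generator's truth
#' table.
#'
#' @param objects `objects` from [segmentReference].
#' @param truth ground-truth table from [renderImageSeries] (rows with
#'   `class_label != "debris"` are the cells to recover).
#' @return a list: `precision`, `recall`, `nMatched`, plus the matched pairs.
#' @export
matchDetections <- function(objects, truth) {
  cells <- truth[truth$class_label != "debris", , drop = FALSE]
  matched <- rep(NA_integer_, nrow(objects))
  used <- rep(FALSE, nrow(cells))
  for (i in seq_len(nrow(objects))) {
    d2 <- (cells$x - objects$x[i])^2 + (cells$y - objects$y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && is.finite(d2[j]) && d2[j] <= cells$radius[j]^2) {
      matched[i] <- j
      used[j] <- TRUE
    }
  }
  tp <- sum(!is.na(matched))
  list(precision = if (nrow(objects)) tp / nrow(objects) else NA_real_,
       recall = if (nrow(cells)) tp / nrow(cells) else NA_real_,
       nMatched = tp,
       pairs = data.frame(object_id = objects$object_id,
                          truth_row = matched))
}
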