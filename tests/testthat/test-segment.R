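## helper: paint discs on a constant background
paintField <- function(centers, radii, values, W = 200, H = 160, bg = 500) {
  fr <- matrix(bg, H, W)
  for (i in seq_along(radii)) {
    for (dx in -ceiling(radii[i]):ceiling(radii[i]))
      for (dy in -ceiling(radii[i]):ceiling(radii[i]))
        if (dx^2 + dy^2 <= radii[i]^2)
          fr[centers[i, 2] + dy, centers[i, 1] + dx] <- values[i]
  }
  fr
}

test_that("well-separated discs are found with accurate centroids", {
  ctr <- rbind(c(40, 40), c(120, 60), c(70, 120))
  fr <- paintField(ctr, radii = c(5, 6, 7), values = c(8000, 9000, 10000))
  seg <- segmentReference(fr, segmentationParams())
  expect_equal(nrow(seg$objects), 3L)
  ord <- order(seg$objects$x)
  expect_equal(seg$objects$x[ord], sort(ctr[, 1]), tolerance = 1 / 40)
  expect_equal(seg$objects$y[ord], ctr[order(ctr[, 1]), 2],
               tolerance = 1 / 40)
  ## disjoint pixel sets, in-gate areas
  expect_true(all(seg$objects$area >= 20 & seg$objects$area <= 800))
  expect_equal(sum(seg$labels > 0), sum(seg$objects$area))
})

test_that("the size gate excludes too-small and too-large objects", {
  ctr <- rbind(c(40, 40), c(120, 60), c(70, 120))
  fr <- paintField(ctr, radii = c(2, 6, 30), values = c(9000, 9000, 9000))
  seg <- segmentReference(fr, segmentationParams())
  expect_equal(nrow(seg$objects), 1L)
  expect_equal(seg$objects$x, 120, tolerance = 0.01)
})

test_that("relaxing the minimum area never loses objects", {
  w <- wellSpec("A1", populationSpec("p", 10, nCells = 20L),
                fieldSize = c(250L, 200L), debrisCount = 6L, seed = 13)
  fr <- frames(renderImageSeries(w)$series)[[1]]
  nPrev <- -1L
  for (minA in c(120L, 60L, 30L, 10L)) {
    n <- nrow(segmentReference(fr, segmentationParams(minArea = minA))$objects)
    expect_gte(n, nPrev)
    nPrev <- n
  }
})

test_that("an all-background frame yields an empty result, not an error", {
  fr <- matrix(500, 80, 80)
  seg <- segmentReference(fr, segmentationParams())
  expect_equal(nrow(seg$objects), 0L)
  expect_true(all(seg$labels == 0L))
})

test_that("detection recovers cells but not out-of-gate debris", {
  w <- wellSpec("A1", populationSpec("p", 10.1, nCells = 40L),
                fieldSize = c(348L, 260L), debrisCount = 14L,
                noiseSdFrac = 0.02, seed = 21)
  out <- renderImageSeries(w)
  seg <- segmentReference(frames(out$series)[[1]], segmentationParams())
  m <- matchDetections(seg$objects, out$truth)
  expect_gte(m$precision, 0.95)
  expect_gte(m$recall, 0.95)
})

test_that("measured traces follow fixed ROIs across frames", {
  ## uniform region: constant trace equal to the region value
  frs <- lapply(1:5, function(k) matrix(700, 60, 60))
  frs[[1]][20:30, 20:30] <- 5000
  series <- imageSeries(frs, c(0, 1, 3, 10, 30))
  seg <- segmentReference(frs[[1]], segmentationParams())
  expect_equal(nrow(seg$objects), 1L)
  tr <- measureSeries(seg, series)
  expect_equal(unname(fluorescence(tr)[1, ]), c(5000, rep(700, 4)))
})

test_that("detaching cells collapse to background in measured traces", {
  w <- wellSpec("A1", populationSpec("p", 10, nCells = 12L),
                fieldSize = c(220L, 180L), detachProbability = 0.4,
                noiseSdFrac = 0, seed = 17)
  out <- renderImageSeries(w)
  seg <- segmentReference(frames(out$series)[[1]], segmentationParams())
  tr <- measureSeries(seg, out$series)
  m <- matchDetections(seg$objects, out$truth)
  truth <- out$truth[m$pairs$truth_row, ]
  fl <- fluorescence(tr)
  det <- which(!is.na(truth$detach_frame))
  expect_gt(length(det), 0)
  for (i in det)
    expect_equal(unname(fl[i, ncol(fl)]), 500, tolerance = 1e-6)
})

test_that("shape mismatches between label map and frames are caught", {
  frs <- lapply(1:5, function(k) matrix(700, 60, 60))
  series <- imageSeries(frs, c(0, 1, 3, 10, 30))
  seg <- list(labels = matrix(0L, 30, 30),
              objects = data.frame(object_id = integer(), x = numeric(),
                                   y = numeric(), area = integer()))
  expect_error(measureSeries(seg, series), "shape")
})

test_that("the central-field crop drops peripheral objects", {
  ctr <- rbind(c(8, 8), c(100, 80))
  fr <- paintField(ctr, radii = c(5, 5), values = c(9000, 9000))
  segAll <- segmentReference(fr, segmentationParams())
  segCrop <- segmentReference(fr, segmentationParams(cropFrac = 0.8))
  expect_equal(nrow(segAll$objects), 2L)
  expect_equal(nrow(segCrop$objects), 1L)
  expect_equal(segCrop$objects$x, 100, tolerance = 0.01)
})
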