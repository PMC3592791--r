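test_that("zero-spread population collapses to the specified parameters", {
  spec <- populationSpec("a1", ec50Median = 10.1, ec50LogSd = 0,
                         slopeRange = c(1.2, 1.2), nCells = 5L)
  cells <- samplePopulation(spec, seed = 1)
  expect_equal(cells$true_EC50, rep(10.1, 5))
  expect_equal(cells$true_slope, rep(1.2, 5))
})

test_that("sampled EC50 median converges to the population median", {
  spec <- populationSpec("a2", ec50Median = 49, ec50LogSd = 0.15,
                         nCells = 1000L)
  cells <- samplePopulation(spec, seed = 7)
  expect_lt(abs(median(cells$true_EC50) - 49) / 49, 0.10)
})

test_that("non-responding populations have flat truth", {
  spec <- populationSpec("off", 10, fractionResponders = 0, nCells = 20L)
  cells <- samplePopulation(spec, seed = 2)
  expect_false(any(cells$responder))
  expect_equal(cells$true_dF, rep(0, 20))
  expect_equal(trueResponse(cells[1, ], c(0, 1, 1000)),
               rep(cells$baseline_F[1], 3))
})

test_that("responder fraction matches the spec within binomial error", {
  spec <- populationSpec("mix", 10, fractionResponders = 0.6, nCells = 500L)
  cells <- samplePopulation(spec, seed = 3)
  p <- mean(cells$responder)
  expect_lt(abs(p - 0.6), 3 * sqrt(0.6 * 0.4 / 500))
})

test_that("trueResponse has the Hill asymptotes and midpoint", {
  cell <- data.frame(baseline_F = 1000, true_EC50 = 10, true_slope = 1.3,
                     true_dF = 40, responder = TRUE)
  expect_equal(trueResponse(cell, 0), 1000)
  expect_equal(trueResponse(cell, 1e12), 600, tolerance = 1e-6)
  expect_equal(trueResponse(cell, 10), 800)  # (baseline + asymptote)/2
  expect_error(trueResponse(cell, -1), "non-negative")
})

test_that("noise-free traces equal the ground-truth response exactly", {
  w <- quickWell(ec50 = 49, n = 10L, noise = 0, seed = 4)
  tr <- generateTraces(w)
  truth <- as.data.frame(SummarizedExperiment::rowData(tr))
  fl <- fluorescence(tr)
  for (i in seq_len(nrow(truth)))
    expect_equal(unname(fl[i, ]), trueResponse(truth[i, ], LADDER))
})

test_that("detaching cells drop to background from their detach frame", {
  w <- wellSpec("A1", populationSpec("p", 49, nCells = 40L),
                detachProbability = 0.5, noiseSdFrac = 0, seed = 5)
  tr <- generateTraces(w)
  truth <- as.data.frame(SummarizedExperiment::rowData(tr))
  fl <- fluorescence(tr)
  det <- which(!is.na(truth$detach_frame))
  expect_gt(length(det), 0)
  bg <- 0.05 * 10000
  for (i in det) {
    k <- truth$detach_frame[i]
    expect_true(all(fl[i, k:ncol(fl)] == bg))
    expect_true(all(fl[i, seq_len(k - 1)] != bg))
  }
})

test_that("generation is bit-identical for a fixed seed", {
  w <- quickWell(n = 15L, noise = 0.02, seed = 9)
  expect_identical(fluorescence(generateTraces(w)),
                   fluorescence(generateTraces(w)))
  wi <- wellSpec("A1", populationSpec("p", 10, nCells = 8L),
                 fieldSize = c(120L, 100L), debrisCount = 4L, seed = 9)
  expect_identical(frames(renderImageSeries(wi)$series),
                   frames(renderImageSeries(wi)$series))
})

test_that("empty wells render as pure background", {
  w <- wellSpec("A1", populationSpec("p", 10, nCells = 0L),
                nCells = 0L, fieldSize = c(64L, 48L), noiseSdFrac = 0,
                seed = 1)
  out <- renderImageSeries(w)
  for (fr in frames(out$series))
    expect_true(all(fr == 500))  # 5% of the 10000 baseline
})

test_that("a noise-free rendered disc reproduces the truth within rounding", {
  w <- wellSpec("A1", populationSpec("p", 20, nCells = 1L,
                                     ec50LogSd = 0, baselineCv = 0),
                fieldSize = c(96L, 96L), noiseSdFrac = 0, seed = 6)
  out <- renderImageSeries(w)
  truth <- out$truth[1, ]
  seg <- segmentReference(frames(out$series)[[1]], segmentationParams())
  expect_equal(nrow(seg$objects), 1L)
  tr <- measureSeries(seg, out$series)
  expect_equal(unname(fluorescence(tr)[1, ]),
               trueResponse(truth, LADDER), tolerance = 0.5 / 500)
})

test_that("trace-level and image-level generation share one ground truth", {
  w <- wellSpec("A1", populationSpec("p", 49, nCells = 12L),
                fieldSize = c(200L, 160L), seed = 8)
  trTruth <- as.data.frame(SummarizedExperiment::rowData(generateTraces(w)))
  imTruth <- renderImageSeries(w)$truth
  imTruth <- imTruth[imTruth$class_label != "debris", ]
  cols <- c("cell_id", "baseline_F", "true_EC50", "true_slope", "true_dF",
            "responder", "detach_frame")
  expect_equal(trTruth[, cols], imTruth[, cols], ignore_attr = TRUE)
})

test_that("overfilled fields raise a placement error", {
  w <- wellSpec("A1", populationSpec("p", 10, nCells = 300L,
                                     radiusRange = c(6, 8)),
                fieldSize = c(64L, 64L), seed = 1)
  expect_error(renderImageSeries(w), "placement")
})

test_that("invalid specifications name the offending field", {
  expect_error(populationSpec("x", ec50Median = -1), "ec50Median")
  expect_error(populationSpec("x", 10, dFRange = c(-5, 50)), "dFRange")
  expect_error(wellSpec("A1", populationSpec("p", 10),
                        fractions = c(0.5, 0.5)), "fractions")
  expect_error(wellSpec("A1", populationSpec("p", 10),
                        concentrations = c(0, 3, 1, 10, 30)),
               "increasing")
  expect_error(wellSpec("ZZ", populationSpec("p", 10)), "wellId")
})
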