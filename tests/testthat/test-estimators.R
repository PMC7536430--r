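test_that("oracle density delegates to windowed counting of mitoses only", {
  geom <- slideGeometry(1200, 900, 2.5)
  shape <- foiShapeFromPixels(300, 225, 2.5)
  grid <- gridSpec(geom, 50)
  set.seed(51)
  set <- randomAnnotationSet(geom, 30, 20)
  est <- oracleDensity(set, shape, grid)
  direct <- windowedCountMap(filterLabel(set, "mitosis"), geom, shape, grid)
  expect_equal(mapValues(est), mapValues(direct))
  expect_equal(est@provenance, "oracle")

  empty <- annotationSet("e", geom, data.frame(x = numeric(0), y = numeric(0),
                                               label = character(0)))
  expect_true(all(mapValues(oracleDensity(empty, shape, grid)) == 0))

  hnOnly <- randomAnnotationSet(geom, 0, 15)
  expect_true(all(mapValues(oracleDensity(hnOnly, shape, grid)) == 0))
})

test_that("noisy oracle degenerates correctly and is seed-deterministic", {
  geom <- slideGeometry(1200, 900, 2.5)
  shape <- foiShapeFromPixels(300, 225, 2.5)
  grid <- gridSpec(geom, 50)
  set.seed(53)
  set <- randomAnnotationSet(geom, 40, 10)

  clean <- noisyOracle(set, shape, grid, fnRate = 0, fpPerMm2 = 0, seed = 1)
  expect_equal(mapValues(clean), mapValues(oracleDensity(set, shape, grid)))
  expect_equal(clean@provenance, "noisy_oracle")

  gone <- noisyOracle(set, shape, grid, fnRate = 1, fpPerMm2 = 0, seed = 1)
  expect_true(all(mapValues(gone) == 0))

  a <- noisyOracle(set, shape, grid, 0.3, 2, seed = 99)
  b <- noisyOracle(set, shape, grid, 0.3, 2, seed = 99)
  expect_equal(mapValues(a), mapValues(b))
  expect_error(noisyOracle(set, shape, grid, fnRate = 1.2), "fnRate")
})

test_that("thinning retains a binomial fraction of true mitoses", {
  geom <- slideGeometry(2000, 2000, 1)
  set.seed(55)
  set <- randomAnnotationSet(geom, 1000, 0)
  # whole-slide window, single grid cell: map value == retained count
  shape <- foiShapeFromPixels(2000, 2000, 1)
  grid <- gridSpec(geom, 2000, originX = 1000, originY = 1000)
  kept <- vapply(1:50, function(s)
    mapValues(noisyOracle(set, shape, grid, fnRate = 0.3, seed = s))[1, 1],
    numeric(1))
  sigma <- sqrt(1000 * 0.3 * 0.7)         # binomial sd ~ 14.5
  expect_lt(abs(mean(kept) - 700), 4 * sigma / sqrt(50))
  expect_true(all(abs(kept - 700) < 5 * sigma))
})

test_that("detection thresholding keeps the hand-enumerated subset", {
  dets <- data.frame(x = 1:6, y = 1:6,
                     score1 = c(0.9, 0.4, 0.6, 0.95, 0.5, 0.7),
                     score2 = c(0.8, 0.9, 0.4, NA, 0.55, 0.5))
  # t1 = t2 = 0.5: row2 fails stage 1; row3 fails stage 2; rest pass
  kept <- detectionsToPoints(dets, 0.5, 0.5)
  expect_equal(kept$x, c(1, 4, 5, 6))

  expect_equal(nrow(detectionsToPoints(dets, 0, 0)), 6)
  one <- data.frame(x = 1, y = 1, score1 = 0.9, score2 = 0.4)
  expect_equal(nrow(detectionsToPoints(one, 0.5, 0.5)), 0)
  expect_error(detectionsToPoints(dets, 1.5, 0), "thresholds")
})

test_that("detection thresholding is antitone in both thresholds", {
  set.seed(57)
  dets <- data.frame(x = 1:200, y = 1:200, score1 = runif(200),
                     score2 = ifelse(runif(200) < 0.3, NA, runif(200)))
  prev <- NULL
  for (t in seq(0, 1, by = 0.25)) {
    got <- detectionsToPoints(dets, t, t)$x
    if (!is.null(prev)) expect_true(all(got %in% prev))
    prev <- got
  }
})

test_that("segmentation rasters convert to per-disc density units", {
  geom <- slideGeometry(1600, 1200, 1)
  shape <- foiShapeFromPixels(400, 300, 1)
  grid <- gridSpec(geom, 100)
  D <- 4
  blank <- matrix(FALSE, 300, 400)

  expect_true(all(mapValues(segmapToDensity(
    tissueMaskFromMatrix(blank, D), shape, grid, geom, d = 50)) == 0))

  # one complete disc of diameter 50 full-res px, centered at (800, 600)
  disc <- blank
  for (i in 1:300) for (j in 1:400)
    disc[i, j] <- ((j - 0.5) * D - 800)^2 + ((i - 0.5) * D - 600)^2 <= 25^2
  est <- mapValues(segmapToDensity(tissueMaskFromMatrix(disc, D),
                                   shape, grid, geom, d = 50))
  centerVal <- est[6, 8]  # grid center (750, 550); window [550,950)x[400,700)
  expect_gte(centerVal, 0.92)
  expect_lte(centerVal, 1.08)

  # a second disjoint disc in the same window doubles the value
  disc2 <- disc
  for (i in 1:300) for (j in 1:400)
    disc2[i, j] <- disc2[i, j] ||
      ((j - 0.5) * D - 700)^2 + ((i - 0.5) * D - 500)^2 <= 25^2
  est2 <- mapValues(segmapToDensity(tissueMaskFromMatrix(disc2, D),
                                    shape, grid, geom, d = 50))
  expect_equal(est2[6, 8], 2 * centerVal, tolerance = 1e-9)
})

test_that("segmentation of the full annotation set approximates the oracle", {
  geom <- slideGeometry(2000, 1500, 1)
  shape <- foiShapeFromPixels(500, 375, 1)
  grid <- gridSpec(geom, 125)
  set.seed(59)
  # well-separated figures
  pts <- data.frame(x = seq(150, 1850, by = 170),
                    y = round(seq(150, 1350, length.out = 11)))
  set <- annotationSet("s", geom, cbind(pts, label = "mitosis"))
  segDs <- 2
  full <- segmentationTarget(patchFrame(2000 / segDs, 1500 / segDs,
                                        (pts$x - 1000) / segDs,
                                        (pts$y - 750) / segDs),
                             d = 50 / segDs)
  est <- segmapToDensity(tissueMaskFromMatrix(full, segDs), shape, grid,
                         geom, d = 50)
  gt <- oracleDensity(set, shape, grid)
  # within disc-discretization and window-edge clipping error
  expect_lt(max(abs(mapValues(est) - mapValues(gt))), 1.1)
  inner <- mapValues(est)[3:10, 3:14]
  expect_gt(stats::cor(as.vector(inner),
                       as.vector(mapValues(gt)[3:10, 3:14])), 0.9)
})

test_that("detection CSV reader validates columns and score ranges", {
  d <- withr::local_tempdir()
  path <- file.path(d, "det.csv")
  writeLines(c("x,y,score1,score2", "10,20,0.9,0.8", "30,40,0.7,"), path)
  dets <- readDetections(path)
  expect_equal(nrow(dets), 2)
  expect_true(is.na(dets$score2[2]))
  writeLines(c("x,y", "1,2"), path)
  expect_error(readDetections(path), "missing column")
  writeLines(c("x,y,score1", "1,2,1.4"), path)
  expect_error(readDetections(path), "scores")
})
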