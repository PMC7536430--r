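test_that("oracle selection attains the brute-force maximum MC", {
  for (s in 1:6) {
    cfg <- smallConfig(seed = s)
    gen <- generateTissue(cfg)
    set <- generateAnnotations(cfg, gen$tissue)
    geom <- geometryOf(set)
    shape <- foiPixelDims(mpp = cfg@mpp)
    grid <- gridSpec(geom, 100)
    valid <- validMask(gen$tissue, grid, shape, geom)
    if (!any(mapValues(valid))) next
    res <- selectFOI(oracleDensity(set, shape, grid), valid, shape,
                     annotations = set)
    # independent brute force over every valid grid position
    idx <- which(mapValues(valid), arr.ind = TRUE)
    pts <- filterLabel(set, "mitosis")
    best <- max(vapply(seq_len(nrow(idx)), function(k) {
      cx <- gridCentersX(grid)[idx[k, 2]]
      cy <- gridCentersY(grid)[idx[k, 1]]
      mcAtRect(pts, rectFromCenter(cx, cy, shape))
    }, numeric(1)))
    expect_identical(as.numeric(gtMc(res)), as.numeric(best))
    expect_identical(as.numeric(res@estimateValue), as.numeric(best))
  }
})

test_that("ties break to the smallest row, then column", {
  geom <- slideGeometry(400, 400, 1)
  grid <- gridSpec(geom, 100)
  shape <- foiShapeFromPixels(100, 100, 1)
  flat <- new("DensityMap", grid = grid, windowW = 100, windowH = 100,
              values = matrix(2, 4, 4), provenance = "oracle")
  vm <- matrix(FALSE, 4, 4); vm[3, 2] <- TRUE; vm[2, 3] <- TRUE; vm[2, 2] <- TRUE
  valid <- new("ValidMask", mask = vm, grid = grid, coverage = 0.95)
  res <- selectFOI(flat, valid, shape)
  # first valid position in row-major order is (row 2, col 2)
  expect_equal(unname(foiCenter(res)), c(gridCentersX(grid)[2],
                                         gridCentersY(grid)[2]))
})

test_that("selection is invariant under positive affine transforms", {
  cfg <- smallConfig(seed = 17)
  gen <- generateTissue(cfg)
  set <- generateAnnotations(cfg, gen$tissue)
  geom <- geometryOf(set)
  shape <- foiPixelDims(mpp = cfg@mpp)
  grid <- gridSpec(geom, 100)
  valid <- validMask(gen$tissue, grid, shape, geom)
  est <- oracleDensity(set, shape, grid)
  base <- foiCenter(selectFOI(est, valid, shape))
  set.seed(61)
  for (k in 1:20) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0, 50)
    scaled <- new("DensityMap", grid = grid, windowW = est@windowW,
                  windowH = est@windowH, values = a * mapValues(est) + b,
                  provenance = "oracle")
    expect_equal(foiCenter(selectFOI(scaled, valid, shape)), base)
  }
})

test_that("per-patch estimates are smoothed before the argmax", {
  geom <- slideGeometry(1000, 1000, 1)
  grid <- gridSpec(geom, 100)           # 10 x 10 grid
  shape <- foiShapeFromPixels(300, 300, 1)
  set.seed(63)
  raw <- matrix(runif(100), 10, 10)
  raw[5:7, 6:8] <- raw[5:7, 6:8] + 2    # dense block
  est <- new("DensityMap", grid = grid, windowW = 300, windowH = 300,
             values = raw, provenance = "patch")
  valid <- interiorMask(grid, shape, geom)
  res <- selectFOI(est, valid, shape)
  # kernel is ceiling(300/100) = 3 cells; expected center from brute force
  ma <- bfMovingAverage(raw, 3, 3)
  full <- matrix(-Inf, 10, 10)
  full[2:9, 2:9] <- ma
  full[!mapValues(valid)] <- -Inf
  hit <- which(full == max(full), arr.ind = TRUE)[1, ]
  expect_equal(unname(foiCenter(res)),
               c(gridCentersX(grid)[hit[["col"]]],
                 gridCentersY(grid)[hit[["row"]]]))
})

test_that("selection without any valid position errors", {
  geom <- slideGeometry(400, 400, 1)
  grid <- gridSpec(geom, 100)
  shape <- foiShapeFromPixels(100, 100, 1)
  est <- new("DensityMap", grid = grid, windowW = 100, windowH = 100,
             values = matrix(1, 4, 4), provenance = "oracle")
  none <- new("ValidMask", mask = matrix(FALSE, 4, 4), grid = grid,
              coverage = 0.95)
  expect_error(selectFOI(est, none, shape), "no valid")
})

test_that("evaluateSelection counts the selected rectangle's mitoses", {
  geom <- slideGeometry(1000, 800, 1)
  shape <- foiShapeFromPixels(200, 160, 1)
  cells <- data.frame(x = c(500, 510, 490, 520, 100),
                      y = c(400, 410, 390, 420, 100),
                      label = "mitosis")
  set <- annotationSet("s", geom, cells)

  # hand-placed selection over the 4 clustered points
  expect_equal(evaluateSelection(set, c(505, 405), shape), 4)
  # selection in an empty region
  expect_equal(evaluateSelection(set, c(800, 600), shape), 0)
  # rater-selection data.frame input
  sel <- data.frame(rater = "r", group = "BCVP", center_x = 505,
                    center_y = 405)
  expect_equal(evaluateSelection(set, sel, shape), 4)
  # out-of-slide rectangle is clipped with a warning
  expect_warning(mc <- evaluateSelection(set, c(50, 50), shape), "clip")
  expect_equal(mc, 1)

  # consistency with selectFOI on the oracle
  grid <- gridSpec(geom, 40)
  valid <- interiorMask(grid, shape, geom)
  res <- selectFOI(oracleDensity(set, shape, grid), valid, shape,
                   annotations = set)
  expect_equal(evaluateSelection(set, res), gtMc(res))
})

test_that("FOIResult serializes its rectangle to JSON", {
  shape <- foiShapeFromPixels(200, 160, 1)
  res <- new("FOIResult", centerX = 505, centerY = 405, shape = shape,
             estimateValue = 4, gtMc = 4)
  parsed <- jsonlite::fromJSON(foiResultToJson(res))
  expect_equal(parsed$rect$x0, 405)
  expect_equal(parsed$rect$y1, 485)
  expect_equal(parsed$gt_mc, 4)
})
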