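test_that("partial-figure weight reproduces its worked values", {
  expect_equal(gammaWeight(0, 50), 25)
  expect_equal(gammaWeight(60, 50), 0)
  expect_equal(gammaWeight(-50, 50), 50)
  expect_error(gammaWeight(0, 0), "positive")
  expect_error(gammaWeight(0, -3), "positive")
})

test_that("weight is the interval overlap with the negative half-line", {
  set.seed(41)
  for (k in 1:200) {
    d <- runif(1, 1, 120)
    x <- runif(1, -2 * d, 2 * d)
    overlap <- max(0, min(x + d / 2, 0) - (x - d / 2))
    expect_equal(gammaWeight(x, d) / d, overlap / d, tolerance = 1e-12)
  }
})

test_that("weight is a continuous non-increasing ramp bounded by [0, d]", {
  d <- 37
  xs <- seq(-2 * d, 2 * d, length.out = 4001)
  g <- gammaWeight(xs, d)
  expect_true(all(diff(g) <= 1e-12))
  expect_true(all(g >= 0 & g <= d))
  expect_equal(gammaWeight(-d / 2, d), d)
  expect_equal(gammaWeight(d / 2, d), 0)
  expect_lt(max(abs(diff(g))), d * 2 * (xs[2] - xs[1]))  # no jumps
})

test_that("regression target reproduces the worked count values", {
  cfg <- regressionConfig(d = 50, beta = 10)
  expect_equal(regressionTarget(patchFrame(512, 512), cfg), 0)
  # three figures fully interior -> each contributes 1/beta
  p3 <- patchFrame(512, 512, px = c(0, 10, -30), py = c(0, 5, 40))
  expect_equal(regressionTarget(p3, cfg), 0.3)
  # one figure centered on the right edge -> half a figure
  pe <- patchFrame(512, 512, px = 256, py = 0)
  expect_equal(regressionTarget(pe, cfg), 0.05)
})

test_that("regression target times beta equals the 2-D box-overlap oracle", {
  set.seed(43)
  for (k in 1:500) {
    w <- runif(1, 120, 800); h <- runif(1, 120, 800)
    d <- runif(1, 5, 100)
    n <- sample(0:8, 1)
    # include edge- and corner-straddling positions
    px <- runif(n, -w / 2 - d, w / 2 + d)
    py <- runif(n, -h / 2 - d, h / 2 + d)
    C <- regressionTarget(patchFrame(w, h, px, py), regressionConfig(d, 10))
    expect_equal(C * 10, sum(bfBoxOverlap(px, py, w, h, d)),
                 tolerance = 1e-9)
  }
})

test_that("regression target is invariant under joint translation", {
  set.seed(45)
  absX <- runif(5, 0, 5000); absY <- runif(5, 0, 5000)
  toFrame <- function(cx, cy) patchFrame(512, 384, absX - cx, absY - cy)
  c0 <- regressionTarget(toFrame(2500, 2500))
  for (shift in c(-700, 13.5, 211)) {
    cs <- regressionTarget(patchFrame(512, 384,
                                      (absX + shift) - (2500 + shift),
                                      (absY + shift) - (2500 + shift)))
    expect_equal(cs, c0, tolerance = 1e-12)
  }
})

test_that("segmentation target draws discs matching the pixel-distance oracle", {
  # no points -> empty mask
  expect_false(any(segmentationTarget(patchFrame(64, 64), 50)))

  # one centered figure: exhaustive oracle over all pixel centers
  p <- patchFrame(128, 128, px = 0, py = 0)
  m <- segmentationTarget(p, d = 50)
  want <- matrix(FALSE, 128, 128)
  for (i in 1:128) for (j in 1:128)
    want[i, j] <- ((j - 0.5) - 64)^2 + ((i - 0.5) - 64)^2 <= 25^2
  expect_identical(m, want)
  # disc pixel count within the discretization bracket
  expect_gte(sum(m), pi * 24^2)
  expect_lte(sum(m), pi * 26^2)

  # two nearby figures: union of the single-figure masks
  p2 <- segmentationTarget(patchFrame(128, 128, px = c(-5, 5), py = c(0, 0)), 50)
  a <- segmentationTarget(patchFrame(128, 128, px = -5, py = 0), 50)
  b <- segmentationTarget(patchFrame(128, 128, px = 5, py = 0), 50)
  expect_identical(p2, a | b)
})

test_that("patch sampling honors group contracts, bounds and determinism", {
  geom <- slideGeometry(4000, 3000, 0.25)
  set.seed(47)
  cells <- rbind(
    data.frame(x = runif(25, 0, 3999), y = runif(25, 0, 2999),
               label = "mitosis"),
    data.frame(x = runif(25, 0, 3999), y = runif(25, 0, 2999),
               label = "hard_negative"))
  set <- annotationSet("s", geom, cells)

  for (grp in c("with_mitosis", "with_hard_negative")) {
    specs <- sampleTrainingPatches(set, grp, n = 30, patch = c(512, 512),
                                   seed = 7)
    lbl <- if (grp == "with_mitosis") "mitosis" else "hard_negative"
    pts <- filterLabel(set, lbl)
    for (i in seq_len(nrow(specs))) {
      hit <- patchContainsPoint(specs$x[i], specs$y[i], specs$rotation[i],
                                512, 512, pts$x, pts$y)
      expect_true(any(hit))
    }
  }

  # determinism
  a <- sampleTrainingPatches(set, "random", 50, seed = 11)
  b <- sampleTrainingPatches(set, "random", 50, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, sampleTrainingPatches(set, "random", 50, seed = 12)))

  # all rotated patches fully inside the slide
  big <- sampleTrainingPatches(set, "random", 200, seed = 13)
  for (i in seq_len(nrow(big))) {
    th <- big$rotation[i]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    corners <- R %*% rbind(c(-256, 256, 256, -256), c(-256, -256, 256, 256))
    expect_true(all(big$x[i] + corners[1, ] >= 0 &
                    big$x[i] + corners[1, ] < 4000 &
                    big$y[i] + corners[2, ] >= 0 &
                    big$y[i] + corners[2, ] < 3000))
  }
  expect_true(all(big$rotation >= 0 & big$rotation < 2 * pi))

  # unsatisfiable group
  onlyMit <- annotationSet("s", geom,
                           data.frame(x = 100, y = 100, label = "mitosis"))
  expect_error(sampleTrainingPatches(onlyMit, "with_hard_negative", 5),
               "unsatisfiable")
})
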