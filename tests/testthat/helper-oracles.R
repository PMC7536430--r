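# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. Oracles deliberately use plain nested loops /
# closed forms, not the package's integral-image code paths.

# Brute-force windowed count: loop over every grid position.
bfWindowedCount <- function(points, grid, shape) {
  cx <- gridCentersX(grid); cy <- gridCentersY(grid)
  out <- matrix(0, grid@nRows, grid@nCols)
  for (i in seq_along(cy)) for (j in seq_along(cx)) {
    out[i, j] <- mcAtRect(points, rectFromCenter(cx[j], cy[i], shape))
  }
  out
}

# Brute-force valid-mode mean filter.
bfMovingAverage <- function(raster, kw, kh) {
  oR <- nrow(raster) - kh + 1; oC <- ncol(raster) - kw + 1
  out <- matrix(0, oR, oC)
  for (i in seq_len(oR)) for (j in seq_len(oC))
    out[i, j] <- mean(raster[i:(i + kh - 1), j:(j + kw - 1)])
  out
}

# Closed-form fractional overlap of d x d boxes centered at (px, py) with
# the patch [-w/2, w/2] x [-h/2, h/2], in units of one box area.
bfBoxOverlap <- function(px, py, w, h, d) {
  ox <- pmax(0, pmin(px + d / 2, w / 2) - pmax(px - d / 2, -w / 2))
  oy <- pmax(0, pmin(py + d / 2, h / 2) - pmax(py - d / 2, -h / 2))
  ox * oy / d^2
}

# Brute-force binary morphological closing (dilate then erode) with a
# Euclidean disc of the given radius.
bfClose <- function(mask, radius) {
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  shift <- function(m, dy, dx, fill) {
    out <- matrix(fill, nrow(m), ncol(m))
    ri <- seq_len(nrow(m)) - dy; ci <- seq_len(ncol(m)) - dx
    ok_r <- ri >= 1 & ri <= nrow(m); ok_c <- ci >= 1 & ci <= ncol(m)
    out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
    out
  }
  dil <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs)))
    dil <- dil | shift(mask, offs$dy[k], offs$dx[k], FALSE)
  ero <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs)))
    ero <- ero & shift(dil, offs$dy[k], offs$dx[k], TRUE)
  ero
}

# Brute-force tissue fraction of the window at one grid center, counting
# downsampled pixels whose centers fall inside the window.
bfWindowCoverage <- function(tissue, cx, cy, shape) {
  D <- tissue@downsample
  r <- rectFromCenter(cx, cy, shape)
  n <- 0; hit <- 0
  for (i in seq_len(nrow(tissue@mask))) for (j in seq_len(ncol(tissue@mask))) {
    px <- (j - 0.5) * D; py <- (i - 0.5) * D
    if (px >= r[["x0"]] && px < r[["x1"]] && py >= r[["y0"]] && py < r[["y1"]]) {
      n <- n + 1
      hit <- hit + tissue@mask[i, j]
    }
  }
  if (n == 0) 0 else hit / n
}

# Small synthetic configuration used throughout the tests: a 6 x 4.5 mm
# slide analog (2400 x 1800 px at 2.5 um/px) with the default process rates.
smallConfig <- function(seed = 1L, ...) {
  args <- modifyList(list(widthPx = 2400, heightPx = 1800, mpp = 2.5,
                          nTissueBlobs = 5, blobRadiusMean = 450,
                          downsample = 16, seed = seed),
                     list(...))
  do.call(syntheticConfig, args)
}

# Mid-size configuration for hotspot-recovery style checks: 10 x 7.5 mm.
hotspotConfig <- function(seed = 1L, ...) {
  args <- modifyList(list(widthPx = 4000, heightPx = 3000, mpp = 2.5,
                          nTissueBlobs = 6, blobRadiusMean = 800,
                          downsample = 32, seed = seed),
                     list(...))
  do.call(syntheticConfig, args)
}

# Random point table on a slide.
randomPoints <- function(n, geom) {
  data.frame(x = sample.int(geom@widthPx, n, replace = TRUE) - 1,
             y = sample.int(geom@heightPx, n, replace = TRUE) - 1)
}

# Uniform random annotation set with both labels.
randomAnnotationSet <- function(geom, nMit, nHn = 0, slideId = "t") {
  pts <- randomPoints(nMit + nHn, geom)
  pts$label <- rep(c("mitosis", "hard_negative"), c(nMit, nHn))
  annotationSet(slideId, geom, pts)
}

# Variance-to-mean ratio of quadrat counts of a point pattern.
quadratVMR <- function(x, y, geom, nQx = 10, nQy = 10) {
  qx <- pmin(floor(x / (geom@widthPx / nQx)), nQx - 1)
  qy <- pmin(floor(y / (geom@heightPx / nQy)), nQy - 1)
  counts <- tabulate(qy * nQx + qx + 1, nbins = nQx * nQy)
  stats::var(counts) / mean(counts)
}
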