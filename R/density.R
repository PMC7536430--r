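#' Position-dependent windowed mitotic count
#'
#' Computes, for every center on a regular grid, the number of points that
#' fall into the FOI-sized half-open window centered there — the
#' position-dependent ground-truth mitotic count when the points are the
#' mitosis annotations. The map is accumulated with a 2-D difference array
#' and integral-image (cumulative-sum) pass, so the total cost is
#' O(n_points + n_rows * n_cols) and the counts are exact integers.
#'
#' Windows that overhang the slide border count the points of the window
#' clipped to the slide; since all points lie on the slide this equals the
#' unclipped count. A window larger than the slide raises a warning.
#'
#' @param points data.frame with columns `x`, `y` (full-resolution pixels).
#' @param geometry a [SlideGeometry-class].
#' @param shape a [FOIShape-class] (the window).
#' @param grid a [GridSpec-class].
#' @param provenance tag stored on the result (default `"oracle"`).
#' @return A [DensityMap-class].
#' @export
windowedCountMap <- function(points, geometry, shape, grid,
                             provenance = "oracle") {
  if (shape@widthPx > geometry@widthPx || shape@heightPx > geometry@heightPx)
    warning("window is larger than the slide; windows are clipped to the slide")
  w <- shape@widthPx; h <- shape@heightPx
  hw <- floor(w / 2); hh <- floor(h / 2)
  nR <- grid@nRows; nC <- grid@nCols
  acc <- matrix(0, nR + 1, nC + 1)
  if (nrow(points)) {
    px <- points$x; py <- points$y
    if (any(px < 0 | px >= geometry@widthPx | py < 0 | py >= geometry@heightPx))
      stop("points must lie within the slide bounds")
    # window centered at c contains p  <=>  c in (p + hw - w, p + hw]
    jmin <- pmax(floor((px - w + hw - grid@originX) / grid@stride) + 1, 0)
    jmax <- pmin(floor((px + hw - grid@originX) / grid@stride), nC - 1)
    imin <- pmax(floor((py - h + hh - grid@originY) / grid@stride) + 1, 0)
    imax <- pmin(floor((py + hh - grid@originY) / grid@stride), nR - 1)
    keep <- jmin <= jmax & imin <= imax
    if (any(keep)) {
      i0 <- imin[keep] + 1; i1 <- imax[keep] + 2
      j0 <- jmin[keep] + 1; j1 <- jmax[keep] + 2
      addAt <- function(i, j, v) {
        idx <- cbind(i, j)
        agg <- rowsum(v, group = (j - 1) * (nR + 1) + i)
        lin <- as.integer(rownames(agg))
        acc[lin] <<- acc[lin] + agg[, 1]
      }
      addAt(i0, j0, rep(1, length(i0)))
      addAt(i0, j1, rep(-1, length(i0)))
      addAt(i1, j0, rep(-1, length(i0)))
      addAt(i1, j1, rep(1, length(i0)))
    }
  }
  vals <- apply(apply(acc, 2, cumsum), 1, cumsum)  # transposes
  vals <- t(vals)[seq_len(nR), seq_len(nC), drop = FALSE]
  vals <- round(vals)  # exact integers; guard fp drift
  new("DensityMap", grid = grid, windowW = w, windowH = h,
      values = vals, provenance = provenance)
}

#' Mitotic count inside one rectangle
#'
#' Counts points with `x0 <= x < x1` and `y0 <= y < y1` (half-open on the
#' right/bottom edges).
#'
#' @param points data.frame with columns `x`, `y`.
#' @param rect rectangle `c(x0, y0, x1, y1)` as from [rectFromCenter()].
#' @return Integer count.
#' @export
mcAtRect <- function(points, rect) {
  if (!nrow(points)) return(0L)
  sum(points$x >= rect[["x0"]] & points$x < rect[["x1"]] &
      points$y >= rect[["y0"]] & points$y < rect[["y1"]])
}

#' Valid-mode 2-D moving average
#'
#' Mean filter with a `kernelW x kernelH` box, "valid" mode: the output has
#' shape `(rows - kernelH + 1, cols - kernelW + 1)` and each output element
#' is the mean of the fully covered block. Computed via an integral image.
#'
#' @param raster numeric matrix.
#' @param kernelW,kernelH kernel dimensions in cells (>= 1, <= raster dims).
#' @return Numeric matrix of the reduced size.
#' @export
movingAverage <- function(raster, kernelW, kernelH) {
  r <- nrow(raster); cc <- ncol(raster)
  if (kernelW < 1 || kernelH < 1)
    stop("kernel dimensions must be >= 1")
  if (kernelH > r || kernelW > cc)
    stop("kernel must not be larger than the raster")
  S <- matrix(0, r + 1, cc + 1)
  S[-1, -1] <- t(apply(apply(raster, 2, cumsum), 1, cumsum))
  oR <- r - kernelH + 1; oC <- cc - kernelW + 1
  i <- seq_len(oR); j <- seq_len(oC)
  (S[i + kernelH, j + kernelW, drop = FALSE] -
   S[i, j + kernelW, drop = FALSE] -
   S[i + kernelH, j, drop = FALSE] +
   S[i, j, drop = FALSE]) / (kernelW * kernelH)
}

#' Ground-truth MC distribution over valid positions
#'
#' The multiset of density-map values at the valid FOI centers, sorted
#' ascending — the distribution of possible mitotic counts a rater could
#' obtain on the slide, used for grade grouping and percentile scoring.
#'
#' @param map a [DensityMap-class].
#' @param valid a [ValidMask-class] aligned to the same grid.
#' @return Sorted numeric vector.
#' @export
mcDistribution <- function(map, valid) {
  if (!identical(dim(map@values), dim(valid@mask)))
    stop("valid mask is not aligned to the density-map grid")
  if (!any(valid@mask)) stop("no valid FOI position on this slide")
  sort(map@values[valid@mask])
}

#' Write / read a DensityMap as 32-bit float TIFF plus JSON sidecar
#'
#' @param map a [DensityMap-class].
#' @param path output TIFF path; the sidecar is `paste0(path, ".json")`.
#' @return `path` (write) or the [DensityMap-class] (read).
#' @export
writeDensityMap <- function(map, path) {
  vals <- map@values
  scale <- max(vals, 1)
  tiff::writeTIFF(vals / scale, path, bits.per.sample = 32L)
  g <- map@grid
  writeLines(jsonlite::toJSON(list(stride = g@stride,
                                   origin = c(g@originX, g@originY),
                                   n_cols = g@nCols, n_rows = g@nRows,
                                   window_w = map@windowW,
                                   window_h = map@windowH,
                                   value_scale = scale,
                                   provenance = map@provenance),
                              auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeDensityMap
#' @export
readDensityMap <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  vals <- tiff::readTIFF(path) * meta$value_scale
  grid <- new("GridSpec", stride = meta$stride, originX = meta$origin[1],
              originY = meta$origin[2], nCols = as.integer(meta$n_cols),
              nRows = as.integer(meta$n_rows))
  new("DensityMap", grid = grid, windowW = meta$window_w,
      windowH = meta$window_h, values = vals, provenance = meta$provenance)
}
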