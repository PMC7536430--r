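#' Annotation-oracle density estimator
#'
#' The ground-truth upper bound for the estimator interface: the windowed
#' count map of the mitosis-labeled annotation points.
#'
#' @param set an [AnnotationSet-class].
#' @param shape a [FOIShape-class].
#' @param grid a [GridSpec-class].
#' @return A [DensityMap-class] with provenance `"oracle"`.
#' @export
oracleDensity <- function(set, shape, grid) {
  windowedCountMap(filterLabel(set, "mitosis"), set@geometry, shape, grid,
                   provenance = "oracle")
}

#' Noisy-oracle density estimator
#'
#' Emulates detector error for pipeline robustness studies: each true
#' mitosis is dropped independently with probability `fnRate` (false
#' negatives) and spurious points are added as a uniform Poisson process at
#' `fpPerMm2` per mm2 over tissue (false positives), before windowed
#' counting. Deterministic given `seed`.
#'
#' @inheritParams oracleDensity
#' @param fnRate false-negative probability in \\[0, 1\\].
#' @param fpPerMm2 false positives per mm2 (over tissue when `tissue` is
#'   given, over the whole slide otherwise).
#' @param seed integer seed.
#' @param tissue optional [TissueMask-class] restricting false positives.
#' @return A [DensityMap-class] with provenance `"noisy_oracle"`.
#' @export
noisyOracle <- function(set, shape, grid, fnRate = 0, fpPerMm2 = 0,
                        seed = 1L, tissue = NULL) {
  if (fnRate < 0 || fnRate > 1) stop("'fnRate' must be in [0, 1]")
  if (fpPerMm2 < 0) stop("'fpPerMm2' must be >= 0")
  geom <- set@geometry
  pts <- filterLabel(set, "mitosis")
  withr::with_seed(as.integer(seed), {
    if (nrow(pts) && fnRate > 0)
      pts <- pts[runif(nrow(pts)) >= fnRate, , drop = FALSE]
    if (fpPerMm2 > 0) {
      if (is.null(tissue)) {
        areaMm2 <- geom@widthPx * geom@heightPx * (geom@mpp / 1000)^2
        nFp <- rpois(1, fpPerMm2 * areaMm2)
        fp <- data.frame(x = runif(nFp, 0, geom@widthPx - 1e-9),
                         y = runif(nFp, 0, geom@heightPx - 1e-9))
      } else {
        areaMm2 <- tissueAreaMm2(tissue, geom@mpp)
        nFp <- rpois(1, fpPerMm2 * areaMm2)
        fp <- samplePointsInTissue(nFp, tissue, geom)
      }
      pts <- rbind(pts, fp)
    }
  })
  windowedCountMap(pts, geom, shape, grid, provenance = "noisy_oracle")
}

#' Physical tissue area of a mask
#'
#' @param tissue a [TissueMask-class].
#' @param mpp microns per pixel at full resolution.
#' @return Area in mm2.
#' @export
tissueAreaMm2 <- function(tissue, mpp) {
  sum(tissue@mask) * (tissue@downsample * mpp / 1000)^2
}

# Uniform points over the tissue mask (uniform within each tissue pixel),
# clamped to the slide. Uses the current RNG stream.
samplePointsInTissue <- function(n, tissue, geom) {
  idx <- which(tissue@mask)
  if (!length(idx) || n == 0)
    return(data.frame(x = numeric(0), y = numeric(0)))
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  nr <- nrow(tissue@mask)
  i <- (pick - 1) %% nr          # 0-based row
  j <- (pick - 1) %/% nr         # 0-based col
  D <- tissue@downsample
  data.frame(
    x = pmin((j + runif(n)) * D, geom@widthPx - 1e-9),
    y = pmin((i + runif(n)) * D, geom@heightPx - 1e-9))
}

#' Threshold a two-stage detection list to points
#'
#' Keeps detections whose first-stage score reaches `t1` and whose refined
#' second-stage score (when present) reaches `t2`; order-preserving. This is
#' the adapter from an external object detector's output to the density
#' pipeline.
#'
#' @param dets data.frame with columns `x`, `y`, `score1` and optionally
#'   `score2` (NA where the second stage was not run).
#' @param t1,t2 thresholds in \\[0, 1\\] (defaults 0.5).
#' @return data.frame with columns `x`, `y`.
#' @export
detectionsToPoints <- function(dets, t1 = 0.5, t2 = 0.5) {
  if (t1 < 0 || t1 > 1 || t2 < 0 || t2 > 1)
    stop("thresholds must be in [0, 1]")
  s2 <- if ("score2" %in% names(dets)) dets$score2 else rep(NA_real_, nrow(dets))
  keep <- dets$score1 >= t1 & (is.na(s2) | s2 >= t2)
  dets[keep, c("x", "y"), drop = FALSE]
}

#' Read a detection list from CSV `x,y,score1,score2`
#'
#' @param path CSV file path; `score2` column optional.
#' @return data.frame.
#' @export
readDetections <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("x", "y", "score1"), names(df))
  if (length(missing))
    stop("detection CSV is missing column(s): ", paste(missing, collapse = ", "))
  bad <- c(df$score1, if ("score2" %in% names(df)) df$score2)
  if (any(bad < 0 | bad > 1, na.rm = TRUE))
    stop("detection scores must be in [0, 1]")
  df
}

#' Convert a segmentation raster to a density map
#'
#' Turns a binary mitosis-likelihood segmentation of the slide into windowed
#' mitotic-count estimates: the value at each grid center is the
#' segmentation-mask area inside the FOI window (rescaled to full-resolution
#' pixel units) divided by the area of one ideal figure disc,
#' `pi * (d/2)^2` — i.e. "how many figure discs' worth of mask" the window
#' holds.
#'
#' @param mask a [TissueMask-class]-style binary raster: a logical matrix
#'   wrapped with its downsample factor via [tissueMaskFromMatrix()].
#' @param shape a [FOIShape-class].
#' @param grid a [GridSpec-class].
#' @param geometry a [SlideGeometry-class].
#' @param d figure-disc diameter in full-resolution pixels (default 50).
#' @return A [DensityMap-class] with provenance `"segmentation"`.
#' @export
segmapToDensity <- function(mask, shape, grid, geometry, d = 50) {
  wt <- windowTissueFraction(mask, grid, shape, geometry)
  D <- mask@downsample
  w <- shape@widthPx; h <- shape@heightPx
  # mask pixels inside each window, rescaled to full-resolution area units
  vals <- wt$count * D^2 / (pi * (d / 2)^2)
  vals[vals < 0] <- 0
  new("DensityMap", grid = grid, windowW = w, windowH = h,
      values = vals, provenance = "segmentation")
}
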