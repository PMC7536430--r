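#' Patch frame for target construction
#'
#' A training patch of size `w x h` pixels with mitotic-figure positions
#' given relative to the patch center.
#'
#' @param w,h patch dimensions in pixels.
#' @param px,py numeric vectors of figure positions relative to the center.
#' @return A list of class `"PatchFrame"`.
#' @export
patchFrame <- function(w, h, px = numeric(0), py = numeric(0)) {
  if (w <= 0 || h <= 0) stop("patch dimensions must be positive")
  if (length(px) != length(py)) stop("px and py must have equal length")
  structure(list(w = w, h = h, px = px, py = py), class = "PatchFrame")
}

#' Partial-figure boundary weight
#'
#' Piecewise-linear ramp assigning each mitotic figure a weight according to
#' its positional offset `x` from the patch border (per axis): `d` when the
#' figure (modelled as a `d`-wide box) lies fully inside, `d/2 - x` when it
#' straddles the border, and 0 once it lies fully outside. Equivalently,
#' `gammaWeight(x, d) / d` is the fractional overlap of the interval
#' `[x - d/2, x + d/2]` with the half-line `(-Inf, 0]`. The ramp is the
#' continuous trapezoid resolution of the overlapping branch conditions in
#' the published piecewise definition, which makes the count target below
#' the exact fractional box overlap — the stated purpose of including
#' partial figures in patch border regions.
#'
#' @param x signed positional offset in pixels (vectorized); for a figure at
#'   relative position p on a patch of width w this is `abs(p) - w/2`.
#' @param d approximated mitotic-figure diameter in pixels.
#' @return Weight(s) in \\[0, d\\].
#' @examples
#' gammaWeight(0, 50)    # 25: figure centered on the border
#' gammaWeight(-50, 50)  # 50: fully inside
#' gammaWeight(60, 50)   # 0: fully outside
#' @export
gammaWeight <- function(x, d) {
  if (length(d) != 1 || !is.finite(d) || d <= 0)
    stop("'d' must be a single positive number")
  ifelse(x <= -d / 2, d, ifelse(x < d / 2, d / 2 - x, 0))
}

#' Regression configuration
#'
#' @param d approximated mitotic-figure diameter in pixels (default 50 px at
#'   0.25 um/px, matching the segmentation disc diameter).
#' @param beta normalization divisor of the count target (default 10,
#'   a heuristic scale bringing typical patch counts into \\[0, 1\\]).
#' @return A list of class `"RegressionConfig"`.
#' @export
regressionConfig <- function(d = 50, beta = 10) {
  if (d <= 0) stop("'d' must be positive")
  if (beta <= 0) stop("'beta' must be positive")
  structure(list(d = d, beta = beta), class = "RegressionConfig")
}

#' Normalized mitotic-count regression target
#'
#' The training target for direct count regression on a patch:
#' `C = (1/beta) * sum_i gamma(|px_i| - w/2, d) * gamma(|py_i| - h/2, d) / d^2`.
#' Each summand is the fractional overlap of a `d x d` box centered on the
#' figure with the patch, so a figure fully inside contributes exactly
#' `1/beta` and figures straddling the border contribute their visible
#' fraction.
#'
#' @param patch a [patchFrame()].
#' @param cfg a [regressionConfig()].
#' @return Non-negative scalar `C`.
#' @examples
#' p <- patchFrame(512, 512, px = c(0, 10, -30), py = c(0, 5, 40))
#' regressionTarget(p, regressionConfig())  # 0.3: three interior figures
#' @export
regressionTarget <- function(patch, cfg = regressionConfig()) {
  if (!length(patch$px)) return(0)
  gx <- gammaWeight(abs(patch$px) - patch$w / 2, cfg$d)
  gy <- gammaWeight(abs(patch$py) - patch$h / 2, cfg$d)
  sum(gx * gy) / (cfg$d^2 * cfg$beta)
}

#' Segmentation target map
#'
#' Binary `h x w` raster with a filled disc of diameter `d` (default 50 px)
#' at every mitotic-figure position: pixel centers within Euclidean distance
#' `d/2` of a figure are set. Pixel (row i, col j), 1-based, has its center
#' at `(j - 0.5, i - 0.5)` in patch coordinates with origin at the patch's
#' top-left corner.
#'
#' @param patch a [patchFrame()] (positions relative to the patch center).
#' @param d disc diameter in pixels.
#' @return Logical matrix `h x w`.
#' @export
segmentationTarget <- function(patch, d = 50) {
  w <- round(patch$w); h <- round(patch$h)
  out <- matrix(FALSE, h, w)
  if (!length(patch$px)) return(out)
  cx <- patch$px + patch$w / 2
  cy <- patch$py + patch$h / 2
  r <- d / 2
  for (k in seq_along(cx)) {
    # over-covering bounding box; the distance test decides per pixel
    j0 <- max(floor(cx[k] - r) - 1, 0); j1 <- min(ceiling(cx[k] + r) + 1, w)
    i0 <- max(floor(cy[k] - r) - 1, 0); i1 <- min(ceiling(cy[k] + r) + 1, h)
    if (j1 <= j0 || i1 <= i0) next
    jj <- (j0 + 1):j1; ii <- (i0 + 1):i1
    dx <- (jj - 0.5) - cx[k]; dy <- (ii - 0.5) - cy[k]
    hit <- outer(dy^2, dx^2, "+") <= r^2
    out[ii, jj] <- out[ii, jj] | hit
  }
  out
}

#' Sample training-patch specifications from a slide
#'
#' Draws `n` patch placements `(x, y, rotation)` from one of three sampling
#' groups: patches guaranteed to contain at least one mitotic figure,
#' patches containing at least one hard-negative cell, and unconditioned
#' random patches. Rotation is uniform in \\[0, 2*pi) and is applied about
#' the patch center before cropping; containment of the conditioning cell
#' and of the patch within the slide is evaluated in the rotated frame.
#' Deterministic given `seed`.
#'
#' @param set an [AnnotationSet-class].
#' @param group `"with_mitosis"`, `"with_hard_negative"` or `"random"`.
#' @param n number of patches.
#' @param patch integer pair `c(w, h)` in pixels (default 512 x 512).
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y` (patch center, full-resolution
#'   pixels) and `rotation` (radians).
#' @export
sampleTrainingPatches <- function(set, group = c("with_mitosis",
                                                 "with_hard_negative",
                                                 "random"),
                                  n, patch = c(512, 512), seed = 1L) {
  group <- match.arg(group)
  geom <- set@geometry
  w <- patch[1]; h <- patch[2]
  targets <- switch(group,
    with_mitosis = filterLabel(set, "mitosis"),
    with_hard_negative = filterLabel(set, "hard_negative"),
    random = NULL)
  if (!is.null(targets) && !nrow(targets))
    stop("group '", group, "' is unsatisfiable: no such cell on the slide")
  halfDiag <- sqrt(w^2 + h^2) / 2
  if (2 * halfDiag > min(geom@widthPx, geom@heightPx))
    stop("patch does not fit inside the slide under arbitrary rotation")
  withr::with_seed(as.integer(seed), {
    res <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      for (try in seq_len(10000L)) {
        theta <- runif(1, 0, 2 * pi)
        if (is.null(targets)) {
          cx <- runif(1, halfDiag, geom@widthPx - halfDiag)
          cy <- runif(1, halfDiag, geom@heightPx - halfDiag)
        } else {
          i <- sample.int(nrow(targets), 1)
          # place the cell at a uniform position u in the rotated patch frame
          u <- c(runif(1, -w / 2, w / 2), runif(1, -h / 2, h / 2))
          R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
          c0 <- c(targets$x[i], targets$y[i]) - as.vector(R %*% u)
          cx <- c0[1]; cy <- c0[2]
        }
        if (rotatedPatchInside(cx, cy, theta, w, h, geom)) break
        if (try == 10000L) stop("could not place a patch inside the slide")
      }
      res[k, ] <- c(cx, cy, theta)
    }
    data.frame(x = res[, 1], y = res[, 2], rotation = res[, 3])
  })
}

rotatedPatchInside <- function(cx, cy, theta, w, h, geom) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  corners <- R %*% rbind(c(-w, w, w, -w) / 2, c(-h, -h, h, h) / 2)
  x <- cx + corners[1, ]; y <- cy + corners[2, ]
  all(x >= 0 & x < geom@widthPx & y >= 0 & y < geom@heightPx)
}

#' Is a slide point inside a rotated patch?
#'
#' Maps the point into the patch's rotated frame and tests the axis-aligned
#' bounds; used to verify the containment contract of
#' [sampleTrainingPatches()].
#'
#' @param cx,cy patch center (slide pixels).
#' @param rotation rotation angle in radians.
#' @param w,h patch dimensions.
#' @param px,py point in slide pixels (vectorized).
#' @return Logical vector.
#' @export
patchContainsPoint <- function(cx, cy, rotation, w, h, px, py) {
  dx <- px - cx; dy <- py - cy
  qx <- cos(rotation) * dx + sin(rotation) * dy
  qy <- -sin(rotation) * dx + cos(rotation) * dy
  abs(qx) <= w / 2 & abs(qy) <= h / 2
}

#' Write patch specifications as CSV `x,y,rotation_rad`
#'
#' @param specs data.frame from [sampleTrainingPatches()].
#' @param path output CSV path.
#' @export
writePatchSpecs <- function(specs, path) {
  df <- data.frame(x = specs$x, y = specs$y, rotation_rad = specs$rotation)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
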