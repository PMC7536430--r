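#' Tissue segmentation of a low-resolution slide render
#'
#' Estimates the slide area filled by tissue: the RGB render is converted to
#' grayscale (channel mean), a pixel is tissue iff its intensity falls below
#' the Otsu threshold of the grayscale histogram (tissue is darker than the
#' white background on a brightfield slide), and the binary mask is cleaned
#' by morphological closing with a disk structuring element.
#'
#' @param rgb RGB array `h x w x 3` with values in \\[0, 1\\] (as returned by
#'   `png::readPNG`), or a grayscale matrix.
#' @param downsample integer downsample factor of the render relative to
#'   full resolution (default 32; tissue extent is low-frequency).
#' @param closingRadius disk radius in pixels at the render's scale
#'   (default 5).
#' @return A [TissueMask-class]. A degenerate (uniform) image yields an
#'   all-background mask with a warning.
#' @export
tissueMask <- function(rgb, downsample = 32L, closingRadius = 5L) {
  if (length(dim(rgb)) == 3) {
    gray <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  } else {
    gray <- rgb
  }
  if (!length(gray)) stop("empty image")
  if (diff(range(gray)) == 0) {
    warning("uniform image: degenerate histogram, returning all-background mask")
    return(tissueMaskFromMatrix(matrix(FALSE, nrow(gray), ncol(gray)),
                                downsample))
  }
  thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  mask <- gray < thr
  if (closingRadius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closingRadius) + 1L, "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0.5
  }
  tissueMaskFromMatrix(mask, downsample)
}

# Integral image of a logical/numeric matrix, with a zero row/col prepended.
integralImage <- function(m) {
  S <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  S
}

# Fraction of tissue pixels whose centers fall inside each grid window.
# Returns list(frac, inside): matrices over the grid.
windowTissueFraction <- function(tissue, grid, shape, geometry) {
  D <- tissue@downsample
  S <- integralImage(tissue@mask)
  nr <- nrow(tissue@mask); nc <- ncol(tissue@mask)
  w <- shape@widthPx; h <- shape@heightPx
  cx <- gridCentersX(grid); cy <- gridCentersY(grid)
  x0 <- cx - floor(w / 2); y0 <- cy - floor(h / 2)
  # downsampled pixel j (0-based) has center (j + 0.5) * D
  j0 <- pmax(ceiling(x0 / D - 0.5), 0)
  j1 <- pmin(ceiling((x0 + w) / D - 0.5) - 1, nc - 1)
  i0 <- pmax(ceiling(y0 / D - 0.5), 0)
  i1 <- pmin(ceiling((y0 + h) / D - 0.5) - 1, nr - 1)
  nColsIn <- outer(rep(1, grid@nRows), pmax(j1 - j0 + 1, 0))
  nRowsIn <- outer(pmax(i1 - i0 + 1, 0), rep(1, grid@nCols))
  npix <- nRowsIn * nColsIn
  J0 <- outer(rep(1, grid@nRows), j0); J1 <- outer(rep(1, grid@nRows), j1)
  I0 <- outer(i0, rep(1, grid@nCols)); I1 <- outer(i1, rep(1, grid@nCols))
  cnt <- S[cbind(c(I1 + 2), c(J1 + 2))] - S[cbind(c(I0 + 1), c(J1 + 2))] -
         S[cbind(c(I1 + 2), c(J0 + 1))] + S[cbind(c(I0 + 1), c(J0 + 1))]
  cnt <- matrix(cnt, grid@nRows, grid@nCols)
  frac <- ifelse(npix > 0, cnt / pmax(npix, 1), 0)
  cnt <- ifelse(npix > 0, cnt, 0)
  inside <- outer(y0 >= 0 & (y0 + h) <= geometry@heightPx,
                  x0 >= 0 & (x0 + w) <= geometry@widthPx, "&")
  list(frac = frac, count = cnt, inside = inside)
}

#' Valid-FOI-center mask (the >= 95% tissue-coverage filter)
#'
#' For each grid center, the tissue-pixel fraction of the FOI window is
#' computed from the downsampled tissue mask (via an integral image, the
#' moving-average equivalent for a constant window); the center is valid iff
#' the fraction is at least `coverage` (inclusive) and the window lies fully
#' inside the slide. This excludes FOI picks in slide border areas that are
#' not covered by tissue to at least the threshold.
#'
#' @param tissue a [TissueMask-class].
#' @param grid a [GridSpec-class].
#' @param shape a [FOIShape-class].
#' @param geometry a [SlideGeometry-class].
#' @param coverage tissue-fraction threshold in (0, 1\\] (default 0.95).
#' @return A [ValidMask-class].
#' @export
validMask <- function(tissue, grid, shape, geometry, coverage = 0.95) {
  if (coverage <= 0 || coverage > 1) stop("'coverage' must be in (0, 1]")
  wt <- windowTissueFraction(tissue, grid, shape, geometry)
  new("ValidMask", mask = wt$frac >= coverage & wt$inside,
      grid = grid, coverage = coverage)
}

#' All-tissue valid mask
#'
#' Valid mask of a slide assumed fully covered by tissue: a center is valid
#' iff its window lies fully inside the slide. Equals [validMask()] in the
#' `coverage -> 0+` limit.
#'
#' @inheritParams validMask
#' @return A [ValidMask-class].
#' @export
interiorMask <- function(grid, shape, geometry, coverage = 0.95) {
  w <- shape@widthPx; h <- shape@heightPx
  x0 <- gridCentersX(grid) - floor(w / 2)
  y0 <- gridCentersY(grid) - floor(h / 2)
  inside <- outer(y0 >= 0 & (y0 + h) <= geometry@heightPx,
                  x0 >= 0 & (x0 + w) <= geometry@widthPx, "&")
  new("ValidMask", mask = inside, grid = grid, coverage = coverage)
}

#' Write / read a binary mask as PNG (0/255) with a JSON sidecar
#'
#' @param mask a [TissueMask-class].
#' @param path output PNG path; sidecar at `paste0(path, ".json")`.
#' @export
writeTissueMask <- function(mask, path) {
  png::writePNG(mask@mask * 1, path)
  writeLines(jsonlite::toJSON(list(downsample = mask@downsample),
                              auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeTissueMask
#' @export
readTissueMask <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  tissueMaskFromMatrix(m > 0.5, meta$downsample)
}
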