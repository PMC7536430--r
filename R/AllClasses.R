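#' @import methods
#' @importFrom stats quantile rpois runif rbinom sd cor
#' @importFrom utils read.csv write.csv
NULL

#' Slide geometry
#'
#' Pixel dimensions and physical resolution of a whole-slide image (WSI).
#' Coordinates throughout the package are 0-based, origin at the top-left
#' corner, x rightward, y downward; rectangles are half-open.
#'
#' @slot widthPx slide width in pixels at full resolution.
#' @slot heightPx slide height in pixels at full resolution.
#' @slot mpp microns per pixel (isotropic).
#' @export
setClass("SlideGeometry",
  representation(widthPx = "numeric", heightPx = "numeric", mpp = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@widthPx) != 1 || object@widthPx <= 0 ||
        object@widthPx != round(object@widthPx))
      msg <- c(msg, "'widthPx' must be a single positive integer")
    if (length(object@heightPx) != 1 || object@heightPx <= 0 ||
        object@heightPx != round(object@heightPx))
      msg <- c(msg, "'heightPx' must be a single positive integer")
    if (length(object@mpp) != 1 || !is.finite(object@mpp) || object@mpp <= 0)
      msg <- c(msg, "'mpp' must be a single positive number")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a SlideGeometry
#'
#' @param widthPx,heightPx slide dimensions in pixels.
#' @param mpp microns per pixel; the default 0.25 um/px corresponds to a
#'   typical 400x-scan resolution.
#' @return A [SlideGeometry-class] object.
#' @examples
#' slideGeometry(10000, 8000, mpp = 0.25)
#' @export
slideGeometry <- function(widthPx, heightPx, mpp = 0.25) {
  new("SlideGeometry", widthPx = as.numeric(widthPx),
      heightPx = as.numeric(heightPx), mpp = as.numeric(mpp))
}

#' Field-of-interest shape
#'
#' Pixel dimensions of the rectangular field of interest (FOI) used for
#' mitotic counting, derived from a physical area (the standard 10-HPF area
#' of 2.37 mm2) and an aspect ratio at a given resolution.
#'
#' @slot areaMm2 physical area in mm2.
#' @slot aspect integer aspect ratio, width:height.
#' @slot widthPx,heightPx pixel dimensions at full resolution.
#' @slot mpp microns per pixel the dimensions refer to.
#' @export
setClass("FOIShape",
  representation(areaMm2 = "numeric", aspect = "numeric",
                 widthPx = "numeric", heightPx = "numeric", mpp = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@widthPx < 1 || object@heightPx < 1)
      msg <- c(msg, "pixel dimensions must be >= 1")
    if (length(object@aspect) != 2 || any(object@aspect <= 0))
      msg <- c(msg, "'aspect' must be two positive numbers")
    else if (abs(object@widthPx - object@heightPx * object@aspect[1] / object@aspect[2]) > 1)
      msg <- c(msg, "pixel dims deviate from the aspect ratio by more than 1 px")
    areaPx <- object@areaMm2 * 1e6 / object@mpp^2
    if (abs(object@widthPx * object@heightPx - areaPx) > 0.001 * areaPx)
      msg <- c(msg, "pixel dims deviate from the requested area by more than 0.1%")
    if (is.null(msg)) TRUE else msg
  }
)

#' Regular grid of candidate FOI centers
#'
#' Discretization of the slide into candidate window-center positions,
#' spaced `stride` pixels apart starting at (`originX`, `originY`).
#'
#' @slot stride pixel spacing between adjacent grid centers.
#' @slot originX,originY pixel coordinates of the first grid center.
#' @slot nCols,nRows grid extent.
#' @export
setClass("GridSpec",
  representation(stride = "numeric", originX = "numeric", originY = "numeric",
                 nCols = "integer", nRows = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@stride < 1) msg <- c(msg, "'stride' must be >= 1")
    if (object@nCols < 1 || object@nRows < 1)
      msg <- c(msg, "grid must have at least one row and one column")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a GridSpec covering a slide
#'
#' Grid centers are placed at `origin + k * stride` for k = 0, 1, ... while
#' they remain on the slide. The default origin `floor(stride/2)` centers the
#' grid cells on the pixel lattice.
#'
#' @param geometry a [SlideGeometry-class].
#' @param stride spacing in full-resolution pixels (default 50 px, far below
#'   the FOI dimensions so the discretization error of the maximum is small).
#' @param originX,originY first center (defaults `floor(stride/2)`).
#' @return A [GridSpec-class].
#' @export
gridSpec <- function(geometry, stride = 50,
                     originX = floor(stride / 2), originY = floor(stride / 2)) {
  stopifnot(is(geometry, "SlideGeometry"))
  if (stride < 1) stop("'stride' must be >= 1")
  nCols <- floor((geometry@widthPx - 1 - originX) / stride) + 1
  nRows <- floor((geometry@heightPx - 1 - originY) / stride) + 1
  if (nCols < 1 || nRows < 1) stop("grid origin lies outside the slide")
  new("GridSpec", stride = stride, originX = originX, originY = originY,
      nCols = as.integer(nCols), nRows = as.integer(nRows))
}

#' @describeIn gridSpec x coordinates of all grid-center columns.
#' @param grid a [GridSpec-class].
#' @export
gridCentersX <- function(grid) grid@originX + (seq_len(grid@nCols) - 1) * grid@stride

#' @describeIn gridSpec y coordinates of all grid-center rows.
#' @export
gridCentersY <- function(grid) grid@originY + (seq_len(grid@nRows) - 1) * grid@stride

#' Windowed mitotic-count density map
#'
#' A raster over a [GridSpec-class] whose value at each grid center is the
#' (estimated or exact) mitotic count of the FOI-sized window centered there.
#' The `provenance` tag records which estimator produced the map: `"oracle"`
#' (annotation ground truth), `"noisy_oracle"`, `"detection"`,
#' `"segmentation"`, or `"patch"` for raw per-patch estimates that still
#' require the moving-average step.
#'
#' @slot grid the [GridSpec-class] the raster is aligned to.
#' @slot windowW,windowH window (10-HPF) dimensions in pixels.
#' @slot values numeric matrix, `nRows x nCols`, non-negative.
#' @slot provenance character tag.
#' @export
setClass("DensityMap",
  representation(grid = "GridSpec", windowW = "numeric", windowH = "numeric",
                 values = "matrix", provenance = "character"),
  prototype(provenance = "oracle"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@values),
                   c(object@grid@nRows, object@grid@nCols)))
      msg <- c(msg, "raster shape must be (nRows, nCols)")
    if (any(object@values < 0)) msg <- c(msg, "values must be non-negative")
    if (!object@provenance %in%
        c("oracle", "noisy_oracle", "detection", "segmentation", "patch"))
      msg <- c(msg, "unknown provenance tag")
    if (is.null(msg)) TRUE else msg
  }
)

#' Binary tissue mask
#'
#' Boolean raster marking tissue at a stated integer downsample factor:
#' mask element (i, j) (1-based row/col) covers full-resolution pixels
#' `[ (j-1)*downsample, j*downsample ) x [ (i-1)*downsample, i*downsample )`.
#'
#' @slot mask logical matrix (rows = y, cols = x).
#' @slot downsample integer downsample factor relative to full resolution.
#' @export
setClass("TissueMask",
  representation(mask = "matrix", downsample = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@mask)) msg <- c(msg, "'mask' must be logical")
    if (object@downsample < 1 || object@downsample != round(object@downsample))
      msg <- c(msg, "'downsample' must be a positive integer")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname TissueMask-class
#' @param mask logical matrix.
#' @param downsample integer downsample factor.
#' @export
tissueMaskFromMatrix <- function(mask, downsample = 1L) {
  new("TissueMask", mask = mask, downsample = as.numeric(downsample))
}

#' Valid-FOI-center mask
#'
#' Boolean raster aligned to a [GridSpec-class]: TRUE where the FOI window
#' centered at the grid position lies fully on the slide and is covered by
#' tissue to at least `coverage` (default 0.95, inclusive).
#'
#' @slot mask logical matrix aligned to the grid.
#' @slot grid the [GridSpec-class].
#' @slot coverage the tissue-fraction threshold used.
#' @export
setClass("ValidMask",
  representation(mask = "matrix", grid = "GridSpec", coverage = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@mask)) msg <- c(msg, "'mask' must be logical")
    if (!identical(dim(object@mask), c(object@grid@nRows, object@grid@nCols)))
      msg <- c(msg, "mask shape must match the grid")
    if (object@coverage <= 0 || object@coverage > 1)
      msg <- c(msg, "'coverage' must be in (0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' Labeled cell annotations of one slide
#'
#' Point annotations of mitotic figures and hard-negative look-alike cells
#' (non-mitotic cells with mitosis-like morphology), in full-resolution pixel
#' coordinates.
#'
#' @slot slideId character identifier.
#' @slot geometry the slide's [SlideGeometry-class].
#' @slot cells data.frame with columns `x`, `y` (integer pixels) and
#'   `label` (one of `"mitosis"`, `"hard_negative"`).
#' @export
setClass("AnnotationSet",
  representation(slideId = "character", geometry = "SlideGeometry",
                 cells = "data.frame"),
  validity = function(object) {
    msg <- NULL
    cells <- object@cells
    if (!all(c("x", "y", "label") %in% names(cells)))
      msg <- c(msg, "'cells' must have columns x, y, label")
    else {
      if (!all(cells$label %in% c("mitosis", "hard_negative")))
        msg <- c(msg, "labels must be 'mitosis' or 'hard_negative'")
      bad <- which(cells$x < 0 | cells$x >= object@geometry@widthPx |
                   cells$y < 0 | cells$y >= object@geometry@heightPx)
      if (length(bad))
        msg <- c(msg, sprintf("cell row %d lies outside the slide bounds", bad[1]))
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname AnnotationSet-class
#' @param slideId character slide identifier.
#' @param geometry a [SlideGeometry-class].
#' @param cells data.frame with columns `x`, `y`, `label`.
#' @export
annotationSet <- function(slideId, geometry, cells) {
  cells <- as.data.frame(cells)
  if (nrow(cells) == 0)
    cells <- data.frame(x = numeric(0), y = numeric(0), label = character(0))
  new("AnnotationSet", slideId = as.character(slideId), geometry = geometry,
      cells = cells[, c("x", "y", "label")])
}

#' Selected field of interest
#'
#' The outcome of FOI selection: the chosen window center, its shape, the
#' estimator value that won the argmax, and the ground-truth mitotic count
#' (MC) of the selected rectangle (NA when no annotations were supplied).
#'
#' @slot centerX,centerY selected center in full-resolution pixels.
#' @slot shape the [FOIShape-class] of the window.
#' @slot estimateValue estimator value at the argmax.
#' @slot gtMc ground-truth MC of the selected rectangle, or NA.
#' @export
setClass("FOIResult",
  representation(centerX = "numeric", centerY = "numeric", shape = "FOIShape",
                 estimateValue = "numeric", gtMc = "numeric"))

#' Synthetic-slide configuration
#'
#' Parameters of the synthetic fixture generator: irregular tissue blobs and
#' a Thomas cluster point process (Poisson parents, Gaussian-displaced
#' Poisson offspring) restricted to tissue, emulating the patchy spatial
#' distribution of mitotic figures observed in mast-cell-tumor slides.
#' Rates are per mm2 of tissue.
#'
#' @slot widthPx,heightPx slide dimensions in pixels.
#' @slot mpp microns per pixel.
#' @slot nTissueBlobs number of tissue blobs.
#' @slot blobRadiusMean mean blob radius in pixels.
#' @slot parentRate cluster parents per mm2 of tissue.
#' @slot offspringMean expected mitotic figures per cluster.
#' @slot clusterSigma isotropic Gaussian spread of a cluster, pixels.
#' @slot backgroundRate uniform background mitoses per mm2 of tissue.
#' @slot hardNegativeRate hard negatives per mm2 of tissue.
#' @slot downsample tissue-raster downsample factor.
#' @slot seed integer random seed.
#' @export
setClass("SyntheticConfig",
  representation(widthPx = "numeric", heightPx = "numeric", mpp = "numeric",
                 nTissueBlobs = "numeric", blobRadiusMean = "numeric",
                 parentRate = "numeric", offspringMean = "numeric",
                 clusterSigma = "numeric", backgroundRate = "numeric",
                 hardNegativeRate = "numeric", downsample = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@widthPx <= 0 || object@heightPx <= 0)
      msg <- c(msg, "slide dimensions must be positive")
    rates <- c(object@parentRate, object@offspringMean, object@clusterSigma,
               object@backgroundRate, object@hardNegativeRate)
    if (any(rates < 0)) msg <- c(msg, "rates must be >= 0")
    if (object@nTissueBlobs < 0) msg <- c(msg, "'nTissueBlobs' must be >= 0")
    if (is.null(msg)) TRUE else msg
  }
)

## ---- accessors ----

#' @describeIn SlideGeometry-class slide dimensions as c(width, height).
#' @param object,x an object of the documented class.
#' @export
setGeneric("slideDims", function(object) standardGeneric("slideDims"))
#' @rdname SlideGeometry-class
#' @export
setMethod("slideDims", "SlideGeometry",
          function(object) c(width = object@widthPx, height = object@heightPx))

#' Raster values of a map or mask
#' @param object a DensityMap, TissueMask or ValidMask.
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname mapValues
#' @export
setMethod("mapValues", "DensityMap", function(object) object@values)
#' @rdname mapValues
#' @export
setMethod("mapValues", "TissueMask", function(object) object@mask)
#' @rdname mapValues
#' @export
setMethod("mapValues", "ValidMask", function(object) object@mask)

#' Grid of a map or mask
#' @param object a DensityMap or ValidMask.
#' @export
setGeneric("gridOf", function(object) standardGeneric("gridOf"))
#' @rdname gridOf
#' @export
setMethod("gridOf", "DensityMap", function(object) object@grid)
#' @rdname gridOf
#' @export
setMethod("gridOf", "ValidMask", function(object) object@grid)

#' @describeIn AnnotationSet-class the cell table.
#' @export
setGeneric("cellPoints", function(object) standardGeneric("cellPoints"))
#' @rdname AnnotationSet-class
#' @export
setMethod("cellPoints", "AnnotationSet", function(object) object@cells)

#' @describeIn AnnotationSet-class the slide geometry.
#' @export
setGeneric("geometryOf", function(object) standardGeneric("geometryOf"))
#' @rdname AnnotationSet-class
#' @export
setMethod("geometryOf", "AnnotationSet", function(object) object@geometry)

#' @describeIn FOIResult-class selected center as c(x, y).
#' @export
setGeneric("foiCenter", function(object) standardGeneric("foiCenter"))
#' @rdname FOIResult-class
#' @export
setMethod("foiCenter", "FOIResult",
          function(object) c(x = object@centerX, y = object@centerY))

#' @describeIn FOIResult-class ground-truth MC of the selected rectangle.
#' @export
setGeneric("gtMc", function(object) standardGeneric("gtMc"))
#' @rdname FOIResult-class
#' @export
setMethod("gtMc", "FOIResult", function(object) object@gtMc)

## ---- show methods ----

setMethod("show", "SlideGeometry", function(object) {
  cat(sprintf("SlideGeometry: %d x %d px @ %.4g um/px (%.1f x %.1f mm)\n",
              object@widthPx, object@heightPx, object@mpp,
              object@widthPx * object@mpp / 1000,
              object@heightPx * object@mpp / 1000))
})

setMethod("show", "FOIShape", function(object) {
  cat(sprintf("FOIShape: %d x %d px (%.3g mm2, aspect %g:%g, %.4g um/px)\n",
              object@widthPx, object@heightPx, object@areaMm2,
              object@aspect[1], object@aspect[2], object@mpp))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d centers, stride %g px, origin (%g, %g)\n",
              object@nRows, object@nCols, object@stride,
              object@originX, object@originY))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap [%s]: %d x %d grid, window %d x %d px, max %.3g\n",
              object@provenance, nrow(object@values), ncol(object@values),
              object@windowW, object@windowH, max(object@values)))
})

setMethod("show", "TissueMask", function(object) {
  cat(sprintf("TissueMask: %d x %d @ downsample %d, %.1f%% tissue\n",
              nrow(object@mask), ncol(object@mask), object@downsample,
              100 * mean(object@mask)))
})

setMethod("show", "ValidMask", function(object) {
  cat(sprintf("ValidMask: %d x %d grid, coverage >= %.2f, %d valid centers\n",
              nrow(object@mask), ncol(object@mask), object@coverage,
              sum(object@mask)))
})

setMethod("show", "AnnotationSet", function(object) {
  tab <- table(factor(object@cells$label,
                      levels = c("mitosis", "hard_negative")))
  cat(sprintf("AnnotationSet '%s': %d mitoses, %d hard negatives on %d x %d px\n",
              object@slideId, tab[["mitosis"]], tab[["hard_negative"]],
              object@geometry@widthPx, object@geometry@heightPx))
})

setMethod("show", "FOIResult", function(object) {
  cat(sprintf("FOIResult: center (%g, %g), estimate %.4g, ground-truth MC %s\n",
              object@centerX, object@centerY, object@estimateValue,
              ifelse(is.na(object@gtMc), "NA", format(object@gtMc))))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0("SyntheticConfig: %d x %d px @ %g um/px, %g blobs,\n",
                     "  parents %g/mm2 x %g offspring (sigma %g px), ",
                     "background %g/mm2, hard negatives %g/mm2, seed %d\n"),
              object@widthPx, object@heightPx, object@mpp, object@nTissueBlobs,
              object@parentRate, object@offspringMean, object@clusterSigma,
              object@backgroundRate, object@hardNegativeRate, object@seed))
})
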