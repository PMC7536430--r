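#' Select the field of interest from a density estimate
#'
#' The selection head of the pipeline: the position of the maximal estimator
#' value within the valid mask becomes the FOI center. Estimators that
#' already emit windowed counts over the 10-HPF area (oracle, noisy oracle,
#' detection and segmentation adapters) need no further smoothing and the
#' moving-average step is the identity; raw per-patch estimates (provenance
#' `"patch"`) are first passed through the valid-mode moving average with a
#' kernel of `ceiling(windowW / stride) x ceiling(windowH / stride)` grid
#' cells (ceiling, so the 10-HPF area is never under-covered). Ties are
#' broken deterministically: smallest row index, then smallest column index.
#'
#' Since only the argmax position matters, the selection is invariant under
#' any positive affine transform `a * est + b` of the estimate — a
#' consistent over- or underestimation by the density estimator acts like a
#' scaling factor or an offset and does not move the selected FOI.
#'
#' @param est a [DensityMap-class].
#' @param valid a [ValidMask-class] on the same grid.
#' @param shape the [FOIShape-class] of the FOI.
#' @param annotations optional [AnnotationSet-class]; when given, the
#'   ground-truth MC of the selected rectangle is filled into the result.
#' @return A [FOIResult-class].
#' @export
selectFOI <- function(est, valid, shape, annotations = NULL) {
  grid <- est@grid
  if (!identical(dim(est@values), dim(valid@mask)))
    stop("estimator grid and valid mask are not aligned")
  vals <- est@values
  if (est@provenance == "patch") {
    kw <- ceiling(shape@widthPx / grid@stride)
    kh <- ceiling(shape@heightPx / grid@stride)
    kw <- min(kw, ncol(vals)); kh <- min(kh, nrow(vals))
    ma <- movingAverage(vals, kw, kh)
    full <- matrix(-Inf, nrow(vals), ncol(vals))
    # MA output (i, j) covers grid rows i..i+kh-1; map to the block center
    full[seq_len(nrow(ma)) + floor((kh - 1) / 2),
         seq_len(ncol(ma)) + floor((kw - 1) / 2)] <- ma
    vals <- full
  }
  vals[!valid@mask] <- -Inf
  if (all(is.infinite(vals))) stop("no valid FOI position")
  best <- max(vals)
  hits <- which(vals == best, arr.ind = TRUE)
  pick <- hits[order(hits[, 1], hits[, 2])[1], ]
  cx <- gridCentersX(grid)[pick[["col"]]]
  cy <- gridCentersY(grid)[pick[["row"]]]
  gt <- NA_real_
  if (!is.null(annotations))
    gt <- suppressWarnings(evaluateSelection(annotations, c(cx, cy), shape))
  new("FOIResult", centerX = cx, centerY = cy, shape = shape,
      estimateValue = best, gtMc = as.numeric(gt))
}

#' Ground-truth mitotic count of a selection
#'
#' Counts the mitosis annotations inside the FOI rectangle of a selection —
#' the measure by which rater and algorithmic FOI choices are compared. A
#' rectangle extending outside the slide is clipped with a warning.
#'
#' @param set an [AnnotationSet-class].
#' @param sel a [FOIResult-class], a numeric center `c(x, y)`, or a one-row
#'   data.frame with columns `center_x`, `center_y` (a rater selection).
#' @param shape the [FOIShape-class]; defaults to the shape stored in a
#'   [FOIResult-class] selection.
#' @return Integer ground-truth MC.
#' @export
evaluateSelection <- function(set, sel, shape = NULL) {
  if (is(sel, "FOIResult")) {
    if (is.null(shape)) shape <- sel@shape
    center <- c(sel@centerX, sel@centerY)
  } else if (is.data.frame(sel)) {
    center <- c(sel$center_x[1], sel$center_y[1])
  } else {
    center <- as.numeric(sel[1:2])
  }
  if (is.null(shape)) stop("'shape' is required for non-FOIResult selections")
  rect <- rectFromCenter(center[1], center[2], shape)
  geom <- set@geometry
  if (rect[["x0"]] < 0 || rect[["y0"]] < 0 ||
      rect[["x1"]] > geom@widthPx || rect[["y1"]] > geom@heightPx) {
    warning("selection rectangle extends outside the slide; clipping")
    rect <- clipRect(rect, geom)
  }
  mcAtRect(filterLabel(set, "mitosis"), rect)
}

#' Serialize an FOIResult as JSON
#'
#' @param res a [FOIResult-class].
#' @return JSON string with the rectangle in full-resolution pixels.
#' @export
foiResultToJson <- function(res) {
  rect <- rectFromCenter(res@centerX, res@centerY, res@shape)
  jsonlite::toJSON(list(center_x = res@centerX, center_y = res@centerY,
                        rect = as.list(rect),
                        estimate_value = res@estimateValue,
                        gt_mc = if (is.na(res@gtMc)) NULL else res@gtMc,
                        shape = jsonlite::fromJSON(foiShapeToJson(res@shape))),
                   auto_unbox = TRUE, digits = NA, null = "null")
}
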