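#' Derive the FOI pixel dimensions from a physical area
#'
#' Solves `w * h = areaMm2 * 1e6 / mpp^2` and `w : h = aspect` for the pixel
#' dimensions of the field of interest, rounding each to the nearest integer.
#' With the veterinary-pathology standard 10-HPF area of 2.37 mm2 at 4:3 and
#' 0.25 um/px this yields a 7111 x 5333 px window.
#'
#' @param areaMm2 physical window area in mm2 (default 2.37, the standard
#'   10-HPF counting area).
#' @param aspect integer pair, width:height (default `c(4, 3)`).
#' @param mpp microns per pixel (default 0.25).
#' @return A [FOIShape-class].
#' @examples
#' foiPixelDims()                      # 7111 x 5333 px
#' foiPixelDims(2.37, c(1, 1), 1.0)    # 1539 x 1539 px
#' @export
foiPixelDims <- function(areaMm2 = 2.37, aspect = c(4, 3), mpp = 0.25) {
  if (length(areaMm2) != 1 || !is.finite(areaMm2) || areaMm2 <= 0)
    stop("'areaMm2' must be a single positive number")
  if (length(aspect) != 2 || any(!is.finite(aspect)) || any(aspect <= 0))
    stop("'aspect' must be two positive numbers")
  if (length(mpp) != 1 || !is.finite(mpp) || mpp <= 0)
    stop("'mpp' must be a single positive number")
  areaPx <- areaMm2 * 1e6 / mpp^2
  w <- round(sqrt(areaPx * aspect[1] / aspect[2]))
  h <- round(sqrt(areaPx * aspect[2] / aspect[1]))
  new("FOIShape", areaMm2 = areaMm2, aspect = as.numeric(aspect),
      widthPx = w, heightPx = h, mpp = mpp)
}

#' Construct an FOIShape from explicit pixel dimensions
#'
#' Convenience constructor for non-standard windows (tests, small synthetic
#' slides): the physical area is derived from the dimensions.
#'
#' @param widthPx,heightPx window dimensions in pixels.
#' @param mpp microns per pixel.
#' @return A [FOIShape-class] whose `areaMm2` matches the pixel dims exactly.
#' @export
foiShapeFromPixels <- function(widthPx, heightPx, mpp = 0.25) {
  if (widthPx < 1 || heightPx < 1) stop("pixel dimensions must be >= 1")
  g <- gcd2(round(widthPx), round(heightPx))
  new("FOIShape", areaMm2 = widthPx * heightPx * mpp^2 / 1e6,
      aspect = c(round(widthPx) / g, round(heightPx) / g),
      widthPx = round(widthPx), heightPx = round(heightPx), mpp = mpp)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Half-open rectangle centered at a point
#'
#' Returns the FOI rectangle `[cx - floor(w/2), cx - floor(w/2) + w) x
#' [cy - floor(h/2), cy - floor(h/2) + h)`. The rectangle may extend outside
#' the slide; clipping is the caller's concern.
#'
#' @param cx,cy center in pixels.
#' @param shape a [FOIShape-class].
#' @return Named numeric vector `c(x0, y0, x1, y1)` (x1, y1 exclusive).
#' @examples
#' rectFromCenter(100, 100, foiShapeFromPixels(10, 6))
#' @export
rectFromCenter <- function(cx, cy, shape) {
  w <- shape@widthPx
  h <- shape@heightPx
  x0 <- cx - floor(w / 2)
  y0 <- cy - floor(h / 2)
  c(x0 = x0, y0 = y0, x1 = x0 + w, y1 = y0 + h)
}

#' Clip a rectangle to the slide bounds
#'
#' @param rect rectangle as returned by [rectFromCenter()].
#' @param geometry a [SlideGeometry-class].
#' @return The intersection rectangle (may be empty: x1 <= x0).
#' @export
clipRect <- function(rect, geometry) {
  c(x0 = max(rect[["x0"]], 0), y0 = max(rect[["y0"]], 0),
    x1 = min(rect[["x1"]], geometry@widthPx),
    y1 = min(rect[["y1"]], geometry@heightPx))
}

#' Serialize / deserialize an FOIShape as JSON
#'
#' @param shape a [FOIShape-class].
#' @return `foiShapeToJson`: a JSON string with keys area_mm2, aspect,
#'   width_px, height_px, mpp. `foiShapeFromJson`: the [FOIShape-class].
#' @export
foiShapeToJson <- function(shape) {
  jsonlite::toJSON(list(area_mm2 = shape@areaMm2, aspect = shape@aspect,
                        width_px = shape@widthPx, height_px = shape@heightPx,
                        mpp = shape@mpp),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname foiShapeToJson
#' @param json a JSON string produced by [foiShapeToJson()].
#' @export
foiShapeFromJson <- function(json) {
  x <- jsonlite::fromJSON(json)
  new("FOIShape", areaMm2 = x$area_mm2, aspect = as.numeric(x$aspect),
      widthPx = x$width_px, heightPx = x$height_px, mpp = x$mpp)
}
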