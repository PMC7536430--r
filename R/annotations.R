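#' Read cell annotations from CSV plus JSON sidecar
#'
#' The canonical on-disk format is a CSV with mandatory header
#' `slide,x,y,label` and a JSON sidecar (`<path>.json` by default) supplying
#' the slide geometry as `{slide_id, width_px, height_px, mpp}`. Rows with
#' labels other than `mitosis` / `hard_negative` are rejected, as are
#' out-of-bounds coordinates (bounds are half-open: `x == width_px` is out).
#'
#' @param path CSV file path.
#' @param sidecar path of the geometry sidecar; default `paste0(path, ".json")`.
#' @return An [AnnotationSet-class].
#' @export
readAnnotations <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (!file.exists(sidecar)) stop("geometry sidecar not found: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  need <- c("slide_id", "width_px", "height_px", "mpp")
  if (!all(need %in% names(meta)))
    stop("sidecar must supply ", paste(need, collapse = ", "))
  geom <- slideGeometry(meta$width_px, meta$height_px, meta$mpp)

  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("slide", "x", "y", "label")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("annotation CSV is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df)) {
    badLabel <- which(!df$label %in% c("mitosis", "hard_negative"))
    if (length(badLabel))
      stop(sprintf("row %d has unknown label '%s'", badLabel[1],
                   df$label[badLabel[1]]))
    oob <- which(df$x < 0 | df$x >= geom@widthPx |
                 df$y < 0 | df$y >= geom@heightPx)
    if (length(oob))
      stop(sprintf("row %d: point (%g, %g) lies outside the %d x %d slide",
                   oob[1], df$x[oob[1]], df$y[oob[1]],
                   geom@widthPx, geom@heightPx))
  }
  annotationSet(meta$slide_id, geom,
                data.frame(x = as.numeric(df$x), y = as.numeric(df$y),
                           label = df$label))
}

#' Write cell annotations to CSV plus JSON sidecar
#'
#' Inverse of [readAnnotations()]; `read(write(set))` round-trips
#' coordinates and labels exactly.
#'
#' @param set an [AnnotationSet-class].
#' @param path output CSV path.
#' @param sidecar sidecar path; default `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(set, path, sidecar = paste0(path, ".json")) {
  cells <- set@cells
  df <- data.frame(slide = rep(set@slideId, nrow(cells)),
                   x = cells$x, y = cells$y, label = cells$label)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  geom <- set@geometry
  writeLines(jsonlite::toJSON(list(slide_id = set@slideId,
                                   width_px = geom@widthPx,
                                   height_px = geom@heightPx,
                                   mpp = geom@mpp),
                              auto_unbox = TRUE, digits = NA),
             sidecar)
  invisible(path)
}

#' Extract the points carrying one label
#'
#' @param set an [AnnotationSet-class].
#' @param label `"mitosis"` or `"hard_negative"`.
#' @return Order-preserving data.frame with columns `x`, `y`.
#' @export
filterLabel <- function(set, label = c("mitosis", "hard_negative")) {
  label <- match.arg(label)
  cells <- set@cells
  cells[cells$label == label, c("x", "y"), drop = FALSE]
}

#' Read / write rater FOI selections
#'
#' Rater selections are stored as CSV `rater,group,center_x,center_y`, with
#' an optional `slide` column for multi-slide studies. `group` is one of
#' `BCVP` (board-certified veterinary pathologist), `VPIT` (veterinary
#' pathologist in training) or `algorithm`.
#'
#' @param path CSV file path.
#' @return data.frame with columns `rater`, `group`, `center_x`, `center_y`
#'   (and `slide` if present).
#' @export
readRaterSelections <- function(path) {
  if (!file.exists(path)) stop("selection file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("rater", "group", "center_x", "center_y")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("selection CSV is missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!df$group %in% c("BCVP", "VPIT", "algorithm"))
  if (length(bad))
    stop(sprintf("row %d has unknown rater group '%s'", bad[1], df$group[bad[1]]))
  df
}

#' @rdname readRaterSelections
#' @param selections data.frame as returned by [readRaterSelections()].
#' @export
writeRaterSelections <- function(selections, path) {
  write.csv(selections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
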