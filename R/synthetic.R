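#' Construct a synthetic-slide configuration
#'
#' Defaults describe a mast-cell-tumor-like slide at a 10x-reduced working
#' scale: a 25 x 20 mm slide represented as 10000 x 8000 px at 2.5 um/px,
#' roughly half of it covered by irregular tissue (a few hundred mm2, the
#' magnitude of a large tumor cross-section), mitotic figures arranged as a
#' patchy Thomas cluster process
#' whose hotspots reach mitotic counts around the grading threshold of 7
#' per 10 HPF, plus a diffuse background of figures and a denser background
#' of hard-negative look-alike cells.
#'
#' @param widthPx,heightPx slide dimensions in pixels.
#' @param mpp microns per pixel.
#' @param nTissueBlobs number of tissue blobs.
#' @param blobRadiusMean mean blob radius in pixels.
#' @param parentRate cluster parents per mm2 of tissue.
#' @param offspringMean expected mitoses per cluster.
#' @param clusterSigma Gaussian cluster spread in pixels.
#' @param backgroundRate diffuse background mitoses per mm2.
#' @param hardNegativeRate hard negatives per mm2.
#' @param downsample tissue-raster downsample factor.
#' @param seed integer seed.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(widthPx = 10000, heightPx = 8000, mpp = 2.5,
                            nTissueBlobs = 10, blobRadiusMean = 1200,
                            parentRate = 0.06, offspringMean = 8,
                            clusterSigma = 150, backgroundRate = 0.4,
                            hardNegativeRate = 4, downsample = 32,
                            seed = 1L) {
  new("SyntheticConfig", widthPx = widthPx, heightPx = heightPx, mpp = mpp,
      nTissueBlobs = nTissueBlobs, blobRadiusMean = blobRadiusMean,
      parentRate = parentRate, offspringMean = offspringMean,
      clusterSigma = clusterSigma, backgroundRate = backgroundRate,
      hardNegativeRate = hardNegativeRate, downsample = downsample,
      seed = as.integer(seed))
}

#' Generate irregular synthetic tissue and an H&E-like render
#'
#' Tissue is the union of randomly placed soft-edged discs whose radius is
#' modulated around the circumference by low-order random harmonics (so blob
#' outlines are irregular, like tumor cross-sections). The render colors
#' tissue in an H&E-like pink on a white background, blending linearly over
#' a narrow soft edge; the mask itself is the hard `dist <= r(theta)` set.
#' Deterministic given `cfg@seed`.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return List with elements `tissue` ([TissueMask-class]) and `render`
#'   (RGB array `h x w x 3` at the tissue downsample, values in \\[0, 1\\]).
#' @export
generateTissue <- function(cfg) {
  D <- cfg@downsample
  nc <- ceiling(cfg@widthPx / D); nr <- ceiling(cfg@heightPx / D)
  field <- matrix(-Inf, nr, nc)   # signed inside-depth in ds pixels
  withr::with_seed(cfg@seed, {
    n <- cfg@nTissueBlobs
    if (n > 0) {
      bx <- runif(n, 0.1, 0.9) * nc
      by <- runif(n, 0.1, 0.9) * nr
      br <- cfg@blobRadiusMean / D * runif(n, 0.6, 1.4)
      for (k in seq_len(n)) {
        amp <- runif(3, 0, 0.12); phase <- runif(3, 0, 2 * pi)
        # local window around the blob
        j <- seq(max(1, floor(bx[k] - 1.6 * br[k])),
                 min(nc, ceiling(bx[k] + 1.6 * br[k])))
        i <- seq(max(1, floor(by[k] - 1.6 * br[k])),
                 min(nr, ceiling(by[k] + 1.6 * br[k])))
        dx <- outer(rep(1, length(i)), j - 0.5 - bx[k])
        dy <- outer(i - 0.5 - by[k], rep(1, length(j)))
        dist <- sqrt(dx^2 + dy^2)
        theta <- atan2(dy, dx)
        rim <- br[k] * (1 + amp[1] * cos(2 * theta + phase[1]) +
                            amp[2] * cos(3 * theta + phase[2]) +
                            amp[3] * cos(5 * theta + phase[3]))
        field[i, j] <- pmax(field[i, j], rim - dist)
      }
    }
  })
  mask <- field >= 0
  edge <- pmin(pmax(field / 2 + 0.5, 0), 1)   # soft edge over ~2 ds px
  pink <- c(0.91, 0.72, 0.81)
  render <- array(1, dim = c(nr, nc, 3))
  for (ch in 1:3) render[, , ch] <- 1 - edge * (1 - pink[ch])
  list(tissue = tissueMaskFromMatrix(mask, D), render = render)
}

#' Generate clustered cell annotations on synthetic tissue
#'
#' Realizes a Thomas cluster process restricted to tissue: cluster parents
#' form a Poisson process with intensity `parentRate` per mm2 of tissue,
#' each parent spawns `Poisson(offspringMean)` mitotic figures displaced by
#' an isotropic Gaussian with sd `clusterSigma`, and offspring falling
#' outside tissue (or the slide) are rejected. A diffuse background of
#' mitoses at `backgroundRate` and hard negatives at `hardNegativeRate`
#' (both uniform over tissue) is added. Coordinates are rounded to integer
#' pixels. Deterministic given `seed`.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param tissue a [TissueMask-class] (e.g. from [generateTissue()]).
#' @param slideId slide identifier for the resulting set.
#' @param seed seed; defaults to `cfg@seed + 1` so tissue and points use
#'   distinct streams.
#' @return An [AnnotationSet-class].
#' @export
generateAnnotations <- function(cfg, tissue, slideId = "synthetic",
                                seed = cfg@seed + 1L) {
  geom <- slideGeometry(cfg@widthPx, cfg@heightPx, cfg@mpp)
  areaMm2 <- tissueAreaMm2(tissue, cfg@mpp)
  D <- tissue@downsample
  nr <- nrow(tissue@mask); nc <- ncol(tissue@mask)
  inTissue <- function(x, y) {
    j <- pmin(pmax(floor(x / D), 0), nc - 1) + 1
    i <- pmin(pmax(floor(y / D), 0), nr - 1) + 1
    tissue@mask[cbind(i, j)]
  }
  withr::with_seed(as.integer(seed), {
    mx <- numeric(0); my <- numeric(0)
    if (areaMm2 > 0) {
      nPar <- rpois(1, cfg@parentRate * areaMm2)
      if (nPar > 0) {
        par <- samplePointsInTissue(nPar, tissue, geom)
        nOff <- rpois(nPar, cfg@offspringMean)
        if (sum(nOff) > 0) {
          ox <- rep(par$x, nOff) + stats::rnorm(sum(nOff), 0, cfg@clusterSigma)
          oy <- rep(par$y, nOff) + stats::rnorm(sum(nOff), 0, cfg@clusterSigma)
          keep <- ox >= 0 & ox < geom@widthPx & oy >= 0 & oy < geom@heightPx
          keep[keep] <- inTissue(ox[keep], oy[keep])
          mx <- ox[keep]; my <- oy[keep]
        }
      }
      nBg <- rpois(1, cfg@backgroundRate * areaMm2)
      bg <- samplePointsInTissue(nBg, tissue, geom)
      mx <- c(mx, bg$x); my <- c(my, bg$y)
      nHn <- rpois(1, cfg@hardNegativeRate * areaMm2)
      hn <- samplePointsInTissue(nHn, tissue, geom)
    } else {
      hn <- data.frame(x = numeric(0), y = numeric(0))
    }
    cells <- data.frame(
      x = pmin(round(c(mx, hn$x)), geom@widthPx - 1),
      y = pmin(round(c(my, hn$y)), geom@heightPx - 1),
      label = rep(c("mitosis", "hard_negative"), c(length(mx), nrow(hn))))
    annotationSet(slideId, geom, cells)
  })
}

#' Generate a slide with a planted mitotic hotspot
#'
#' Produces an annotation set whose maximal-MC window is known by
#' construction: on top of the configured background process, `hotspotMc`
#' mitoses are planted uniformly in the central third of a FOI window at a
#' randomly chosen valid center. The precondition that the hotspot dominate
#' any background window is enforced as
#' `hotspotMc >= 2 * E[background window MC] + 10`; below that margin the
#' planted maximum is not guaranteed and an error is raised.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param hotspotMc number of planted mitoses (default 30).
#' @param shape FOI shape; default derived from the standard 10-HPF area at
#'   `cfg@mpp`.
#' @param stride grid stride for choosing the planted center (default 50).
#' @param seed seed; defaults to `cfg@seed`.
#' @return List with elements `set` ([AnnotationSet-class]), `center`
#'   (planted center `c(x, y)`), `tissue` ([TissueMask-class]).
#' @export
generatePlantedHotspot <- function(cfg, hotspotMc = 30, shape = NULL,
                                   stride = 50, seed = cfg@seed) {
  if (is.null(shape)) shape <- foiPixelDims(mpp = cfg@mpp)
  windowMm2 <- shape@widthPx * shape@heightPx * (cfg@mpp / 1000)^2
  expBg <- (cfg@backgroundRate + cfg@parentRate * cfg@offspringMean) * windowMm2
  if (hotspotMc < 2 * expBg + 10)
    stop(sprintf(paste0("hotspotMc = %g does not dominate the expected ",
                        "background window MC %.2f (need >= %.2f)"),
                 hotspotMc, expBg, 2 * expBg + 10))
  cfg@seed <- as.integer(seed)
  gen <- generateTissue(cfg)
  set <- generateAnnotations(cfg, gen$tissue, seed = seed + 1L)
  geom <- set@geometry
  grid <- gridSpec(geom, stride)
  valid <- validMask(gen$tissue, grid, shape, geom)
  if (!any(valid@mask))
    stop("no valid FOI center on the generated slide; cannot plant a hotspot")
  withr::with_seed(as.integer(seed) + 2L, {
    idx <- which(valid@mask, arr.ind = TRUE)
    pick <- idx[sample.int(nrow(idx), 1), ]
    cx <- gridCentersX(grid)[pick[["col"]]]
    cy <- gridCentersY(grid)[pick[["row"]]]
    hx <- round(runif(hotspotMc, cx - shape@widthPx / 6,
                      cx + shape@widthPx / 6))
    hy <- round(runif(hotspotMc, cy - shape@heightPx / 6,
                      cy + shape@heightPx / 6))
  })
  cells <- rbind(set@cells,
                 data.frame(x = hx, y = hy,
                            label = rep("mitosis", hotspotMc)))
  list(set = annotationSet(set@slideId, geom, cells),
       center = c(x = cx, y = cy), tissue = gen$tissue)
}
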