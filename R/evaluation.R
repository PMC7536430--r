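#' Pearson correlation with validity checks
#'
#' Sample product-moment correlation between estimated and ground-truth
#' mitotic counts; since FOI selection only uses the argmax, a consistent
#' scale or offset error of an estimator leaves this measure (and the
#' selection) unchanged, which is why correlation is the appropriate
#' comparison of density estimators.
#'
#' @param xs,ys numeric vectors of equal length >= 2.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation in \\[-1, 1\\].
#' @export
pearsonCorr <- function(xs, ys, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(xs) != length(ys)) stop("'xs' and 'ys' must have equal length")
  if (length(xs) < 2) stop("need at least two observations")
  if (sd(xs) == 0 || sd(ys) == 0)
    stop("undefined correlation: zero variance")
  cor(xs, ys, method = method)
}

#' Cohen's kappa for binary ratings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' marginal-product expected agreement `p_e`. When `p_e == 1` (both raters
#' degenerate on the same margin) the value is 1 for perfect observed
#' agreement and 0 otherwise.
#'
#' @param a,b binary (logical or 0/1) vectors of equal length >= 1.
#' @return Kappa in \\[-1, 1\\].
#' @examples
#' cohenKappa(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0: agreement equals chance
#' @export
cohenKappa <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (!length(a)) stop("need at least one rating")
  a <- as.numeric(as.logical(a)); b <- as.numeric(as.logical(b))
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + (1 - mean(a)) * (1 - mean(b))
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Grade grouping of a slide by its MC distribution
#'
#' Groups a tumor case by the distribution of possible mitotic counts over
#' all valid FOI positions: `clearly_low` when every possible count is below
#' the grading threshold (the FOI choice cannot matter), `clearly_high`
#' when more than `highFrac` of the possible counts reach the threshold,
#' `borderline` otherwise — the regime where FOI placement decides the
#' grade.
#'
#' @param dist MC distribution from [mcDistribution()] (non-empty).
#' @param threshold grading threshold (default 7 mitoses per 10 HPF, the
#'   mast-cell-tumor high-grade criterion).
#' @param highFrac strict lower bound on the above-threshold fraction for
#'   `clearly_high` (default 0.75; exactly 75% is still borderline).
#' @return `"clearly_low"`, `"borderline"` or `"clearly_high"`.
#' @export
gradeGroup <- function(dist, threshold = 7, highFrac = 0.75) {
  if (!length(dist)) stop("empty MC distribution")
  if (all(dist < threshold)) return("clearly_low")
  if (mean(dist >= threshold) > highFrac) return("clearly_high")
  "borderline"
}

#' Percentile score of a selection
#'
#' Where a selection's ground-truth MC sits within the slide's distribution
#' of possible counts: whether it reaches the upper half and the upper
#' quarter. Percentiles use linear interpolation of the empirical
#' distribution function (`quantile` type 4), so on `dist = 1..100` the
#' 75th percentile is exactly 75.
#'
#' @param selectedMc ground-truth MC of the selection.
#' @param dist sorted MC distribution (non-empty).
#' @return Named logical vector `c(top_half, top_quarter)`.
#' @export
percentileScore <- function(selectedMc, dist) {
  if (!length(dist)) stop("empty MC distribution")
  q <- quantile(dist, c(0.5, 0.75), type = 4, names = FALSE)
  c(top_half = selectedMc >= q[1], top_quarter = selectedMc >= q[2])
}

#' Wilson score interval for a proportion
#'
#' @param k successes, `n` trials.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Named numeric `c(estimate, lower, upper)`.
#' @export
wilsonCI <- function(k, n, conf = 0.95) {
  if (n < 1) stop("'n' must be >= 1")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, center - half), upper = min(1, center + half))
}

#' Per-case and per-group rater evaluation report
#'
#' For every slide: the ground-truth MC distribution over valid FOI centers
#' (summarized as min/quartiles/max), its grade group, and for every rater
#' selection the ground-truth MC of the selected rectangle, the
#' above-threshold flag and the upper-half / upper-quarter percentile flags.
#' Per rater group it reports the proportion of selections reaching the
#' upper half and upper quarter (with Wilson 95% CIs) and Cohen's kappa on
#' the above-threshold question — both against the slide's attainable
#' ground truth (`max(dist) >= threshold`) and as the mean pairwise kappa
#' between raters of the group.
#'
#' @param sets list of [AnnotationSet-class] (or a single one).
#' @param selections data.frame with columns `rater`, `group`, `center_x`,
#'   `center_y` and (for multi-slide studies) `slide`.
#' @param shape a [FOIShape-class].
#' @param stride grid stride in pixels (default 50).
#' @param tissues optional named list of [TissueMask-class] per slide; when
#'   absent the all-tissue interior mask is used.
#' @param threshold grading threshold (default 7).
#' @param coverage valid-mask coverage (default 0.95).
#' @return List with elements `cases` (one row per slide x rater) and
#'   `groups` (one row per rater group).
#' @export
raterReport <- function(sets, selections, shape, stride = 50, tissues = NULL,
                        threshold = 7, coverage = 0.95) {
  if (is(sets, "AnnotationSet")) sets <- list(sets)
  names(sets) <- vapply(sets, function(s) s@slideId, character(1))
  if (!"slide" %in% names(selections))
    selections$slide <- names(sets)[1]
  unknown <- setdiff(unique(selections$slide), names(sets))
  if (length(unknown))
    stop("selection references unknown slide id: ", unknown[1])

  perSlide <- lapply(sets, function(set) {
    geom <- set@geometry
    grid <- gridSpec(geom, stride)
    gt <- oracleDensity(set, shape, grid)
    valid <- if (!is.null(tissues) && !is.null(tissues[[set@slideId]]))
      validMask(tissues[[set@slideId]], grid, shape, geom, coverage)
    else interiorMask(grid, shape, geom, coverage)
    dist <- mcDistribution(gt, valid)
    list(dist = dist, grade = gradeGroup(dist, threshold))
  })

  rows <- lapply(seq_len(nrow(selections)), function(i) {
    sel <- selections[i, ]
    set <- sets[[sel$slide]]
    ps <- perSlide[[sel$slide]]
    mc <- suppressWarnings(evaluateSelection(set, sel, shape))
    sc <- percentileScore(mc, ps$dist)
    data.frame(slide = sel$slide, rater = sel$rater, group = sel$group,
               grade_group = ps$grade,
               dist_min = min(ps$dist),
               dist_q25 = quantile(ps$dist, 0.25, type = 4, names = FALSE),
               dist_median = quantile(ps$dist, 0.5, type = 4, names = FALSE),
               dist_q75 = quantile(ps$dist, 0.75, type = 4, names = FALSE),
               dist_max = max(ps$dist),
               gt_mc = mc,
               above_threshold = mc >= threshold,
               gt_above_threshold = max(ps$dist) >= threshold,
               top_half = unname(sc["top_half"]),
               top_quarter = unname(sc["top_quarter"]))
  })
  cases <- do.call(rbind, rows)

  groups <- lapply(split(cases, cases$group), function(g) {
    th <- wilsonCI(sum(g$top_half), nrow(g))
    tq <- wilsonCI(sum(g$top_quarter), nrow(g))
    kTruth <- if (length(unique(g$gt_above_threshold)) >= 1)
      cohenKappa(g$above_threshold, g$gt_above_threshold) else NA_real_
    # mean pairwise kappa between raters of the group, over shared slides
    raters <- unique(g$rater)
    kPair <- NA_real_
    if (length(raters) >= 2) {
      pairs <- utils::combn(raters, 2, simplify = FALSE)
      ks <- vapply(pairs, function(p) {
        a <- g[g$rater == p[1], c("slide", "above_threshold")]
        b <- g[g$rater == p[2], c("slide", "above_threshold")]
        m <- merge(a, b, by = "slide")
        if (!nrow(m)) return(NA_real_)
        cohenKappa(m$above_threshold.x, m$above_threshold.y)
      }, numeric(1))
      kPair <- mean(ks, na.rm = TRUE)
    }
    data.frame(group = g$group[1], n = nrow(g),
               prop_top_half = th[["estimate"]],
               top_half_lower = th[["lower"]], top_half_upper = th[["upper"]],
               prop_top_quarter = tq[["estimate"]],
               top_quarter_lower = tq[["lower"]],
               top_quarter_upper = tq[["upper"]],
               kappa_vs_truth = kTruth, kappa_pairwise = kPair)
  })
  list(cases = cases, groups = do.call(rbind, c(groups, make.row.names = FALSE)))
}
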