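---
title: "Selecting the mitotically most active 10-HPF region of a whole-slide image"
author: "mitospot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the mitotically most active 10-HPF region of a whole-slide image}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitospot)
```

## The problem

The mitotic count (MC) — the number of mitotic figures in a standardized
counting area of ten high-power fields (10 HPF, fixed here at 2.37 mm² with
a 4:3 aspect ratio) — is a central criterion in tumor grading. For canine
cutaneous mast cell tumors, seven or more mitoses per 10 HPF marks the
high-grade class. The count, however, depends strongly on *where* the
counting rectangle is placed: mitotic figures are not spread uniformly
through tumor tissue but cluster in patches, so two raters placing their
field of interest (FOI) differently can land on opposite sides of the
grading threshold. `mitospot` implements the algorithmic counterpart of
this placement task: given point annotations of mitotic figures (or the
output of an external detector), find the FOI with the highest mitotic
density, restricted to windows that actually lie on tissue.

## The pipeline

The package mirrors a two-branch design:

1. **Density branch.** A per-position estimate of the mitotic count of the
   FOI-sized window centered at each position on a regular grid. For
   annotation points this is exact windowed counting
   (`windowedCountMap()`, `oracleDensity()`); for raw per-patch estimates
   a valid-mode 2-D moving average with a kernel equal to the FOI
   dimensions (`movingAverage()`) produces the same quantity up to
   discretization. The selected FOI is the argmax of this map within the
   valid mask (`selectFOI()`).
2. **Valid-mask branch.** A low-resolution render of the slide is
   thresholded (Otsu) and cleaned by morphological closing to produce a
   tissue mask (`tissueMask()`); a candidate FOI center is *valid* iff its
   window is covered by tissue to at least 95% (inclusive) and lies fully
   on the slide (`validMask()`). This keeps the argmax away from slide
   borders and sparse tissue fragments.

Because the selection uses only the argmax, any estimator that is wrong by
a consistent scale or offset still selects the same FOI; `selectFOI()` is
provably invariant under positive affine transforms of the estimate, and
the test suite checks this property directly. Correlation (rather than
absolute error) is therefore the appropriate measure for comparing density
estimators, and `pearsonCorr()` is provided for that purpose.

## Coordinates, grids and numerical conventions

* Coordinates are 0-based, origin top-left, x rightward, y downward;
  rectangles are half-open (`[x0, x1) × [y0, y1)`). A point exactly on the
  left/top edge is counted, on the right/bottom edge it is not.
* FOI pixel dimensions solve `w·h = area/mpp²` and `w:h = aspect`, each
  rounded to the nearest integer (minimizing area error); at 0.25 µm/px
  the standard 2.37 mm² 4:3 window is 7111 × 5333 px. Windows are anchored
  at their center.
* The candidate grid uses a default stride of 50 px at full resolution —
  two orders of magnitude below the FOI dimensions, so the discretization
  error of the maximum is at most a few percent of one window side, while
  maps stay small enough to recompute in milliseconds.
* `windowedCountMap()` accumulates a difference array and two cumulative
  sums (an integral image), so counts are exact integers at
  O(points + grid cells) cost; the tests pin it against brute-force loops.
* Windows overhanging the slide border count points of the clipped window
  (identical to the unclipped count, since points lie on the slide); such
  centers are removed later by the fully-inside condition of the valid
  mask, but the map itself stays total-count consistent.
* Ties in the argmax are broken to the smallest row, then column index, so
  selection is deterministic.

## Tissue masking

Tissue detection operates at a default downsample of 32: tissue extent is
a low-frequency property, and a 32× reduced raster keeps masks tiny. The
threshold is Otsu's method on the grayscale channel mean — parameter-free
and adequate for the brightfield tissue-versus-white-background decision;
the channel is configurable since saturation or optical density can serve
equally. Closing uses a disk of radius 5 at the working scale (≈160 px at
full resolution), enough to bridge small tears and staining gaps without
merging separate fragments. The coverage test is inclusive (≥ 0.95), and
the implementation counts downsampled pixels whose centers fall inside the
window, which agrees with exact pixel counting up to one border pixel of
quantization; the boundary behavior is pinned by tests at coverage
fractions of exactly 0.95 and 0.94 on a downsample-1 mask.

## Training targets

For count regression on an image patch of width `w` and height `h`, each
mitotic figure is modelled as a `d × d` box around its center point, and
the patch target is

\[
C = \frac{1}{\beta}\sum_i
    \frac{\gamma(|p_{x,i}| - w/2)\,\gamma(|p_{y,i}| - h/2)}{d^2},
\]

where `p` are coordinates relative to the patch center and `γ` is a
continuous piecewise-linear ramp: `γ(x) = d` for `x ≤ −d/2`, `d/2 − x` on
`(−d/2, d/2)`, and 0 beyond. With this ramp, each summand is exactly the
fractional overlap of the figure's box with the patch, so figures
straddling a patch border contribute their visible fraction — the stated
purpose of the construction. (The piecewise conditions as usually printed
overlap and cannot hold simultaneously; the trapezoid above is the unique
continuous resolution and is what the package implements. The test suite
verifies the box-overlap identity to 10⁻⁹ on 10,000 random
configurations.) Defaults are `d = 50` px at 0.25 µm/px — matching the
50-px discs used for segmentation targets — and `β = 10`, a heuristic
normalizer bringing typical patch counts into [0, 1].

Segmentation targets (`segmentationTarget()`) are unions of filled discs
of diameter `d` at each figure position, evaluated at pixel centers.
`sampleTrainingPatches()` reproduces the three-group sampling scheme
(patches with a mitosis, with a hard negative, unconditioned) with uniform
rotation in [0, 2π) applied about the patch center before cropping;
containment is evaluated in the rotated frame, and conditioned placements
are found by drawing the conditioning cell's position uniformly within the
rotated patch, which keeps the sampler exact rather than
rejection-biased. Patch size is never standardized in this setting; the
default is 512 × 512 px, configurable.

## Estimators

`oracleDensity()` is the annotation ground truth and the upper bound of
the estimator interface. `noisyOracle()` degrades it with independent
false-negative thinning and a uniform false-positive Poisson process over
tissue — a two-parameter error model sufficient for studying how selection
quality decays with detector quality (selection regret is exactly zero at
zero noise and grows monotonically with the miss rate; both are asserted
in the acceptance tests). `detectionsToPoints()` adapts external two-stage
detector output (keep if `score1 ≥ t1` and, where present, `score2 ≥ t2`;
defaults 0.5/0.5 since operating points are model-specific), and
`segmapToDensity()` converts a binary segmentation raster to density units
by dividing the in-window mask area by the area of one ideal figure disc,
`π(d/2)²`. CNN training and inference themselves are deliberately out of
scope: any model's post-processed output plugs in through these adapters.

## Evaluation

`mcDistribution()` gives the multiset of ground-truth MCs attainable over
all valid FOI centers of a slide — the yardstick against which any
selection (human or algorithmic) is scored. On top of it:

* `gradeGroup()` classifies a case as `clearly_low` (no attainable count
  reaches the threshold — placement cannot matter), `clearly_high` (more
  than 75% of attainable counts reach it; the inequality is strict, so
  exactly 75% is still borderline), or `borderline` — the regime where FOI
  placement decides the grade.
* `percentileScore()` flags whether a selection reaches the upper half and
  upper quarter of the distribution. Percentiles use linear interpolation
  of the empirical distribution function (R's `quantile` type 4), under
  which the 75th percentile of the integers 1…100 is exactly 75; the
  package treats "at the percentile" as reaching it.
* `cohenKappa()` measures chance-corrected agreement on the ≥ 7 question.
  Whether agreement should be scored against the slide's attainable truth
  or pairwise between raters is ambiguous in routine practice, so
  `raterReport()` reports both.
* Proportions come with Wilson score intervals — better behaved than the
  normal approximation at the small group sizes typical of rater studies.
  Pearson correlation is the default association measure, with Spearman
  as an option.

## The synthetic generator

Real annotated whole-slide images are gigapixel objects; the package ships
a generator instead, designed to reproduce the one property that makes FOI
selection non-trivial: a patchy, clustered spatial distribution of mitotic
figures inside irregular tissue. Tissue is a union of soft-edged discs
with harmonically perturbed outlines; mitoses follow a Thomas cluster
process (Poisson parents at `parentRate` per mm² of tissue, each with
Poisson(`offspringMean`) offspring displaced by an isotropic Gaussian of
sd `clusterSigma`), restricted to tissue by rejection, plus a diffuse
uniform background; hard negatives are uniform over tissue.

Defaults model a 25 × 20 mm slide at a 10×-reduced working resolution
(10000 × 8000 px at 2.5 µm/px), about half covered by tissue (a few
hundred mm², the magnitude of a large tumor cross-section), with
`parentRate = 0.06`/mm², `offspringMean = 8`, `clusterSigma = 150` px
(0.375 mm), `backgroundRate = 0.4`/mm² and `hardNegativeRate = 4`/mm².
These rates put typical windows near MC ≈ 2 and hotspot windows around and
above the grading threshold of 7 — the borderline regime where selection
matters. Offspring falling outside tissue are dropped, not resampled, so
realized intensities dip slightly below nominal near tissue edges; the
calibration check therefore uses an all-tissue mask with `clusterSigma`
small against the slide, where the compound-Poisson expectation holds to
well under one standard error.

What the generator does **not** emulate: nucleus-level image texture,
stain variation, necrosis, tissue folds, or the visual ambiguity that
makes real mitosis detection hard. Passing tests therefore demonstrate
that the *selection and evaluation machinery* is correct and robust to
detector-style noise — not that any particular detector performs well on
real histology.

## Problem sizes used by the tests and acceptance script

The test suite and `scripts/acceptance.R` run on reduced slides chosen to
keep a full run in the tens of seconds on a single core while leaving all
rates at their per-mm² study values: 2400 × 1800 px (6 × 4.5 mm) slides
for exactness checks against brute-force oracles, 4000 × 3000 px
(10 × 7.5 mm) slides for hotspot recovery (60–100 seeded replicates),
regret curves (100 seeds per miss rate) and generator calibration
(100–200 seeds). Exact properties (integer count equality, the 10⁻⁹
box-overlap identity) are independent of these sizes; stochastic checks
use enough replicates that their 4σ bands are a few percent wide.

## Known limitations

* Pixel spacing is assumed isotropic; anisotropic scans are out of scope.
* The ground-truth MC window uses the FOI shape (4:3) rather than a
  square of equal area; this is configurable but not varied in the tests.
* `selectFOI()` reports a single FOI; top-k reporting is not implemented.
* The tissue threshold is global (Otsu); slides with extreme staining
  gradients would need a locally adaptive threshold.
* Detection inputs are assumed post-NMS point lists; no non-maximum
  suppression is performed.
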