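Package: mitospot
Title: Field-of-Interest Selection for Mitotic Count Hotspots on Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects the mitotically most active 10-high-power-field (10 HPF)
    region of a tumor whole-slide image from point annotations or external
    detector output. Implements position-dependent ground-truth mitotic count
    maps via integral-image windowed counting, tissue masking with a 95%
    window-coverage valid mask, training-target construction for count
    regression (fractional border weighting) and segmentation (disc maps),
    pluggable density estimators, rater-versus-algorithm evaluation (Pearson
    correlation, Cohen's kappa at the grading threshold, grade grouping,
    percentile scoring), and a clustered spatial point-process simulator for
    synthetic slides with patchy mitotic-figure distributions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    tiff,
    withr,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
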