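Package: ChangeScape
Title: Annual Vegetation Change, Land Cover and Land Use Mapping from
    Dense Reflectance Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale production of annual vegetation-change, land-cover
    and land-use maps from per-pixel multiband reflectance time series.
    Implements geometric medoid compositing with provenance tracking,
    piecewise-linear temporal segmentation (LandTrendr-style) and harmonic
    LASSO change detection (CCDC-style) with run feathering, terrain
    predictors, random-forest class-confidence mapping with grouped
    cross-validated tuning and F1-optimal change thresholds, rule-based map
    assembly with multi-level thematic cross-walks, change-year summary
    layers and QA provenance bits, disproportionate stratified sampling with
    design weights, and design-based weighted accuracy assessment. A
    synthetic-scene generator with known annual truth labels makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    ranger,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
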