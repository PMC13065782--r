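# ChangeScape

Desk-scale production of coincident annual **vegetation Change**, **Land
Cover** and **Land Use** maps from dense multiband reflectance time
series, with a design-based weighted accuracy assessment. The package is
aimed at remote-sensing and landscape-ecology researchers who want the
full national-monitoring-style mapping chain — temporal-model predictors,
random-forest class confidences, thresholded rule-based assembly,
thematic cross-walks, stratified sampling and weighted validation — in a
form that runs end to end on synthetic scenes with known truth, so every
stage is testable without satellite archives.

## The method

For each pixel and year the pipeline derives 133 candidate predictors:

- **Temporal segmentation** (piecewise-linear): each of 14 annual index
  series (6 bands; NDVI, NBR, NDMI, NDSI; tasseled-cap brightness,
  greenness, wetness and angle) from geometric-medoid composites is fit
  with at most 9 connected linear segments, subject to a recovery-rate
  rule (segments recovering faster than `recoveryThreshold` of the series
  range per year are disallowed) and an F-test model screen. Five
  predictors per index: fitted value, difference from the segment start,
  segment magnitude, duration and slope.
- **Harmonic change detection**: per band (6 bands + NDVI), all unmasked
  observations are fit with `b0 + b1 t + sum_k (c_k cos 2 pi k t + s_k
  sin 2 pi k t)`, k = 1..3 cycles/year, by LASSO; a break is declared
  when 6 consecutive observations exceed the chi-square bound
  `qchisq(0.99, 5)` on summed squared normalized residuals over the five
  breakpoint bands. Eight predictors per band, evaluated at the medoid
  composite date. Two overlapping runs can be feathered (linearly
  blended) across a transition window.
- **Terrain**: elevation, Horn slope/aspect (as sine and cosine) and
  topographic position index at 11-, 21- and 41-pixel circular windows.

One random forest per product turns these into per-class **model
confidence** — the proportion of trees voting for the class (100 trees
voting 35/10/5/50 give 0.35/0.10/0.05/0.50). Change classes are assigned
where confidence exceeds an F1-optimal threshold, subject to ancillary
rules, with a Stable fallback; maps are cross-walked to coarser thematic
levels. Accuracy is assessed by grouped, stratified, weighted 10-fold
cross-validation: weighted confusion matrix, overall/balanced accuracy,
user's and producer's accuracies, kappa, and stratified-design standard
errors `Var(OA) = sum_h P_h^2 s_h^2 / n_h`.

## Worked example

```r
library(ChangeScape)
cfg <- pipelineConfig(n_rows = 32, n_cols = 32, year_start = 1994,
                      year_end = 2023, seed = 1)
res <- runPipeline(cfg, quiet = TRUE)

res$cube
#> FeatureCube: 1024 pixels x 30 years x 133 features
#>   blocks: ccdc (56), landtrendr (70), terrain (7)

res$models$products$Change$thresholds
#> Fast Loss      Gain Slow Loss
#>      0.13      0.50      0.41

res$validation$Change$level3
#> ValidationReport (n = 7500): OA 98.84% (SE 0.135), BA 94.73% (SE 0.795), kappa 0.935
res$validation$`Land Use`$level3
#> ValidationReport (n = 7500): OA 100.00% (SE 0.003), BA 99.99% (SE 0.009), kappa 1.000
```

The scene simulates a zoned landscape (forest, shrubland, grassland,
agriculture, developed, water, wetland) with a harvest in 2000, a fire in
2008, an eight-year structural decline, a growth patch and a flood. The
thresholds are the F1-optimal per-class confidence cut-offs chosen on
out-of-bag votes; the validation reports give weighted overall and
balanced accuracy with design-based standard errors over the 7,500
cross-validated plot-year records. Change-year summaries recover the
events: for harvested pixels, `res$summaries$change_years$"Fast Loss"`
puts both the most-recent and peak-confidence Fast Loss year at 2000
(e.g. pixel 1: confidence 0.93).

Maps, confidences and QA layers can be written as multi-directory TIFF
with JSON sidecars (`writeClassMaps()`, `writeRasterStack()`), truth
tables as CSV and designs as JSON. A thin command-line front end over the
same pipeline lives at `inst/scripts/changescape-pipeline.R`.

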