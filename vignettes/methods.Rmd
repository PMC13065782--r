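---
title: "Methods: desk-scale annual change, land cover and land use mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale annual change, land cover and land use mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChangeScape)
```

## What the package computes

ChangeScape produces three coincident annual map products from per-pixel
multiband reflectance time series: vegetation cover **Change** (Fast Loss,
Slow Loss, Gain, Stable), **Land Cover** (physical surface classes and their
successional mixtures) and **Land Use** (management intent). The method is
the standard machine-learning map-production chain used by national
monitoring systems: temporal-model predictors feed a random forest whose
per-class tree-vote proportions ("model confidence") are thresholded and
rule-filtered into final maps, which are then validated with a design-based
weighted accuracy assessment. Everything runs at desk scale on synthetic
scenes with known truth, so every stage is testable end to end without
satellite archives.

## The synthetic scene generator

The generator is first-class, tested code, and its defaults define the
study conditions used throughout the test suite.

A scene is a grid of pixels partitioned into land-use zones (forest,
shrubland, grassland, agriculture, developed, water, wetland), each with a
characteristic six-band reflectance archetype. Per pixel the spectrum is a
mixture `(1 - d) * mature + d * disturbed`, where the annual disturbance
fraction `d` is driven by the event table: abrupt events (fire, harvest)
jump `d` in the event year and relax linearly to zero over the recovery
period; declines ramp `d` up gradually; flooding swaps the disturbance
endpoint to a water spectrum. For fire and harvest the initial `d` is
solved numerically so the NBR drop in the event year equals the configured
magnitude, which makes spectral event signatures exactly checkable.
Within-year seasonality is a first-harmonic sinusoid per band (amplitude
configurable; agriculture amplified) matching the model class of the
harmonic change detector, so harmonic recovery is exactly testable.
Observation dates are drawn uniformly within the compositing window,
sensors are assigned round-robin across the Landsat/Sentinel-2 code set to
exercise QA packing, observations get Gaussian noise and Bernoulli
cloud/shadow masks.

Truth labels follow the joint response design: the change process is Fire,
Harvest, Structural Decline, Growth/Recovery, Hydrology or Stable as
implied by the event trajectory; primary cover follows the successional
ladder (Barren, Grass/Forb/Herbaceous, Shrub, Tree) as a function of `d`,
with the next-higher class recorded as a secondary cover in transition
years; land use is fixed per zone (a fire does not change Forest use).

Defaults: 15 observations per pixel per year, observation noise SD 0.01
reflectance units, 10% masking, a June-September window, and demo events
(harvest magnitude 0.45, fire 0.35, both with 12-year recoveries; an
8-year decline of magnitude 0.2; a growth patch; a 6-year flood). These
are the values a temperate Landsat-class archive would plausibly deliver;
they were chosen once when the generator was written.

What the generator does **not** emulate: radiative-transfer or
illumination effects, spatially correlated cloud structure, sensor
harmonization offsets, mixed pixels at zone borders, and interpreter error
in truth labels. Passing tests therefore demonstrate internal consistency
of the pipeline under a faithful but idealized data model, not real-data
accuracy.

## Compositing

Annual composites are the geometric medoid: the single unmasked
observation minimizing the summed squared deviation from the per-band
medians over green, red, NIR, SWIR1 and SWIR2. All bands of a composite
come from that one acquisition, and its sensor, day of year and fractional
date are tracked as provenance. Ties are broken to the earliest day of
year for determinism. Missing years are filled by per-band linear
interpolation in year (nearest neighbour at the edges) and flagged; the
flag feeds the QA word. Interpolation operates in reflectance space. The
composite date of a filled year is the year plus the median fractional
date of the pixel's valid years; this fallback date is also what the
harmonic model is evaluated at.

Spectral features are NDVI, NBR, NDMI, NDSI, tasseled-cap
brightness/greenness/wetness and the brightness/greenness angle
`atan2(TCG, TCB)` in degrees. The tasseled-cap coefficient set is the
Crist (1985) reflectance-factor matrix and is configurable.

## Temporal segmentation (piecewise-linear)

Each of the 14 annual index series per pixel is fit independently with a
small number of connected linear segments:

1. **Despike.** A spike is a strict one-year local extremum whose two
   flanks are nearly symmetric: the correction proportion `1 - |y[i+1] -
   y[i-1]| / max(|jump up|, |jump down|)` exceeds `spikeThreshold`. Spikes
   are replaced by the neighbour midpoint; at 1.0 nothing is ever damped,
   and genuine trend corners (non-extrema) are never touched.
2. **Vertex oversearch.** Starting from the endpoints, the point of
   maximum absolute residual from the current continuous piecewise-linear
   least-squares fit is inserted until `maxSegments + 1 +
   vertexCountOvershoot` vertices exist, or the fit is exact (so
   noise-free piecewise-linear input recovers its true vertices and
   nothing more).
3. **Prune** back to `maxSegments + 1` vertices by repeatedly removing the
   vertex whose removal least increases the error, producing a nested
   candidate-model sequence on the way down.
4. **Screens.** A candidate is disallowed if any segment moves in the
   recovery direction faster than `recoveryThreshold` of the series range
   per year (0.25 means a full-range recovery quicker than 4 years is
   rejected). Each index carries a recovery orientation (+ for NBR, NDVI,
   NDMI, greenness, wetness, angle and NIR; - for the brightness, SWIR
   and visible bands; the rule can be disabled).
5. **Selection.** Candidate p-values come from the F statistic against the
   mean-only model. Among admissible candidates with p at or below the
   screen (or the minimum p when all fail), the model with the most
   vertices whose p-value is within `bestModelProportion` of the best
   (p <= p_min / bestModelProportion) is chosen. If no candidate is
   admissible the fit falls back to the series mean and is flagged.

The five annual predictors per index are the fitted value, the difference
from the containing segment's start-vertex fitted value, and the segment
magnitude, duration and slope. A vertex year belongs to the segment it
starts; the final year belongs to the last segment. The "difference"
predictor is measured from the containing segment's start (not the series
start); both readings exist in the wild and this one is the local,
scale-free one.

Defaults follow the operational parameter set: maxSegments 9 (raised from
6 so closely spaced breaks are not merged), spikeThreshold 0.9, overshoot
3, recoveryThreshold 0.25, pvalThreshold 0.05, bestModelProportion 0.75.

## Harmonic change detection

Per pixel, all unmasked observations (not composites) of the six bands
plus NDVI are fit with harmonic regression `b0 + b1 t + sum_k (c_k cos 2
pi k t + s_k sin 2 pi k t)`, k = 1..3 cycles/year, by coordinate-descent
LASSO (penalty `lambda` = 0.002 on the reflectance scale, intercept
unpenalized, iteration cap 10000; `lambda` = 0 gives ordinary least
squares). Break detection monitors the five breakpoint bands (green, red,
NIR, SWIR1, SWIR2): an observation's change score is the sum over those
bands of squared residuals normalized by segment RMSE, compared to the
chi-square inverse CDF at probability 0.99 with 5 degrees of freedom. Six
consecutive exceedances declare a break at the first of them; isolated
exceedances are absorbed as outliers. A model initializes on at least 12
observations spanning a year (1.33 years for post-break refits), and the
monitoring model is refit whenever the stable window has grown by 20%
since the last fit. Two guards keep the monitoring calibrated: the
harmonic order adapts to the window (intercept + trend + first harmonic
under 18 observations, two harmonics under 24, all three beyond), and the
RMSE is degrees-of-freedom corrected with a floor of 1e-4 reflectance, so
short windows and noise-free input cannot produce false alarms.

Annual predictors are evaluated at the pixel's medoid composite date: the
fitted value, the fitted difference from the previous year (first year 0
by convention), and the six harmonic coefficients of the segment used.
Within inter-segment gaps the next segment after the break is used; at the
series end the previous segment may extend at most 0.3 years past its last
observation, after which the pixel-year is null and flagged incomplete
rather than imputed.

**Feathering.** When a newer, shorter run overlaps an older archive run,
annual predictor values (not raw coefficients - the blended product is an
annual series) are blended linearly: weight 0 on the new run in 2013
rising to 1 by 2021, with later years fully new. Blended values always lie
between the two inputs.

## Terrain and the predictor cube

Slope and aspect come from Horn's eight-neighbour finite differences with
replicated edges; aspect is measured clockwise from north and encoded as
sine and cosine, both zero on flat cells to avoid undefined values. TPI is
elevation minus the mean within a circular window whose stated size (11,
21, 41 pixels) is treated as the window diameter; windows shrink at raster
edges (mean over valid cells) to avoid nodata halos on small rasters.

The cube stacks 14 x 5 segmentation features, 7 x 8 harmonic features and
7 year-constant terrain features: 133 candidate predictors per pixel-year.
Pixel-years missing any block are flagged incomplete and excluded from
training and prediction; nothing is silently imputed.

## Modeling

Predictor pruning is a two-step correlation filter: pairs with |r| > 0.95
lose their later-registry member, then variables whose mean |r| over all
remaining pairs exceeds 0.95 are dropped; constant columns have undefined
correlations treated as zero. Which member of a pair is dropped is not
specified by convention elsewhere, so the later registry index loses,
making the filter deterministic. Optional recursive feature elimination
scores candidate subsets by grouped 5-fold cross-validated overall
accuracy (dropping the least important 10% per step); optional grid search
tunes trees / minimum leaf / mtry by grouped 10-fold accuracy, ties going
to the smaller model (fewer trees, then larger leaf). Accuracy inside
selection and tuning is unweighted; design weights enter only at
validation.

One random forest per product is trained on the sampled plot-years
(single model, no regionalization). Model confidence is the proportion of
trees voting for a class - 100 trees voting 35/10/5/50 give
0.35/0.10/0.05/0.50 - and sums to 1 per pixel-year. Change thresholds per
class are chosen on the out-of-bag vote fractions by scanning thresholds
0.00-1.00 in 0.01 steps and maximizing F1, ties to the lowest threshold.

## Map assembly and cross-walks

Per pixel-year the candidate classes are those passing their threshold and
not forbidden by a rule; the highest-confidence candidate wins, ties
resolved by a fixed priority list (registry order by default). For Change
only the change classes compete against their thresholds and the pixel
falls back to Stable when none passes; Land Cover and Land Use have no
stable fallback and argmax over all classes subject to rules. Rules are
pure predicates over named ancillary masks with two actions (forbid, or
require a minimum threshold); the default configuration carries one
Change rule forbidding change classes over water, the analogue of a
single national rule preventing change in non-vegetated cover. The same
record-level assembly core is reused verbatim inside the accuracy
assessment so that maps, not bare models, are validated.

Cross-walks are total functions between levels: change processes bin to
Fast Loss / Slow Loss / Gain / Stable (Gain rolls to Stable at Level 1);
land cover pairs a primary with the highest secondary that sits strictly
higher on the succession Barren < Grass/Forb/Herb < Shrub < Tree (Water
and Snow/Ice never mix), then rolls Level 4 mixtures down to 3/2/1; land
use rolls its six classes to broader Anthropogenic / Non-Anthropogenic
levels. Composing level-downs equals the direct table columns, which the
tests assert.

## Summaries and QA

Per change class two summary layers are produced: the most recent
assembled year and the year of maximal model confidence among assembled
years (ties to the earliest). The QA word packs, LSB-first: bit 0 the
not-interpolated flag (0 = interpolated, 1 = not - kept deliberately in
that counterintuitive published orientation), bits 1-5 the sensor code
(4/5/7/8/9 Landsat, 21/22 Sentinel-2a/b), bits 6-14 the Julian day. The
layout round-trips exhaustively; bit compatibility with any distributed
product is explicitly not claimed since published bit numbering does not
fix endianness.

## Sampling design and validation

The loss stratum contains pixels whose NBR segmentation has any segment
magnitude strictly below -0.2 (boundary ties stay stable). Allocation
starts midway between equal and proportional shares, honours fixed counts
and per-stratum caps, re-allocates capped surplus proportionally until
stable, and forces exact totals by largest-remainder rounding. The
published allocation itself is not reproducible (printed counts exceed
stated caps in places), so the tested contract is the weight arithmetic
W_h = (n_h/N)/P_h and exact totals, which the shipped printed design
table reproduces.

Validation is grouped, stratified, weighted 10-fold cross-validation: all
annual records of a plot share a fold; strata are dealt round-robin across
folds; per-record inverse-probability weights are 1/W_h. Predictions are
pooled over folds into a single weighted confusion matrix (not averaged
per fold). Overall accuracy, per-class user's/producer's accuracies,
balanced accuracy (macro-average producer's accuracy) and kappa come from
that matrix. Standard errors are design-based: Var(OA) = sum_h P_h^2
s_h^2 / n_h with s_h^2 the within-stratum variance of the correctness
indicator, and ratio-variance analogues for the per-class accuracies;
balanced-accuracy SE combines producer SEs assuming independence. Annual
records are treated as the analysis unit within strata; the clustering of
records within plots is a known limitation of these SEs. 95% intervals
are estimate +/- 1.96 SE.

## Numerical choices and degenerate inputs

- Segmentation: fewer than 3 valid years gives a flagged flat fallback;
  exact fits stop the vertex search; p = 0 when SSE is numerically zero.
- Harmonic fitting: fewer than 12 observations or under a year of span
  gives a flagged no-model pixel; the RMSE floor is 1e-4.
- Medoid: even-count medians average the middle two; the all-masked
  window yields a null composite, not an error.
- Aspect on flat cells: sine and cosine both 0.
- Allocation: infeasible caps or fixed counts exceeding N are errors;
  stratum counts are additionally capped at stratum pixel counts in the
  pipeline so tiny strata cannot be over-requested.
- All randomness flows through a single master seed; stage seeds are
  derived deterministically, and identical configurations reproduce
  byte-identical maps.

## Problem sizes

The shipped test-suite and acceptance configurations run a 64 x 64 pixel,
30-year scene with 300 sample plots, 300-tree forests and 10-fold
validation - about 1.8 million simulated observations and 123k pixel-years
with 133 predictors - which exercises every stage at a size a laptop
handles comfortably. Module tests use smaller grids chosen for coverage,
not speed alone.

## Worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(n_rows = 32, n_cols = 32, year_start = 1994,
                      year_end = 2023, seed = 1)
res <- runPipeline(cfg)
reportOverall(res$validation$Change$level3)
```

The report prints the weighted overall and balanced accuracy with their
design-based standard errors and kappa for the finest change level;
`res$maps` holds the assembled annual class maps and `res$summaries` the
change-year and QA layers.
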