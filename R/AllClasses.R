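#' @title Core S4 containers
#' @name ChangeScape-classes
#' @description S4 classes holding the central data objects of the mapping
#'   pipeline: scene configuration and simulated scenes, annual composite
#'   series, temporal-model fits, feature and confidence cubes, class map
#'   series, sample designs and validation reports.
NULL

#' Scene configuration for the synthetic generator
#'
#' Holds every knob of the synthetic-scene generator: grid size, year span,
#' observations per year, observation noise, per-band first-harmonic
#' seasonal amplitude, the event table, the compositing window within which
#' observation dates are drawn, the cloud-mask probability, and the seed.
#'
#' @slot n_rows,n_cols grid dimensions in pixels
#' @slot year_start,year_end calendar year span (inclusive)
#' @slot obs_per_year observations simulated per pixel per year
#' @slot noise_sd observation noise standard deviation (reflectance units)
#' @slot seasonal_amplitude named numeric, per-band first-harmonic amplitude
#' @slot events list of events; each has `pixels`, `year`, `kind`
#'   (fire/harvest/decline/growth/hydrology), `magnitude` and optionally
#'   `duration` / `recovery_years`
#' @slot window integer length 2, day-of-year compositing window
#' @slot mask_prob probability an observation is cloud/shadow masked
#' @slot zones integer matrix of land-use zones (0 = use default layout)
#' @slot seed integer RNG seed; identical seeds give identical scenes
#' @export
setClass("SceneConfig", representation(
  n_rows = "integer", n_cols = "integer",
  year_start = "integer", year_end = "integer",
  obs_per_year = "integer", noise_sd = "numeric",
  seasonal_amplitude = "numeric", events = "list",
  window = "integer", mask_prob = "numeric",
  zones = "matrix", seed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@year_end < object@year_start)
    msg <- c(msg, "year_end must be >= year_start")
  if (object@obs_per_year < 1L) msg <- c(msg, "obs_per_year must be >= 1")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (object@mask_prob < 0 || object@mask_prob >= 1)
    msg <- c(msg, "mask_prob must be in [0, 1)")
  if (!identical(names(object@seasonal_amplitude), BAND_NAMES))
    msg <- c(msg, "seasonal_amplitude must be named after the six bands")
  for (ev in object@events) {
    if (length(ev$pixels) == 0)
      msg <- c(msg, "event pixel sets must be non-empty")
    if (!is.null(ev$year) &&
        (ev$year < object@year_start || ev$year > object@year_end))
      msg <- c(msg, sprintf("event year %s outside series", ev$year))
    if (!ev$kind %in% c("fire", "harvest", "decline", "growth", "hydrology"))
      msg <- c(msg, sprintf("unknown event kind '%s'", ev$kind))
  }
  if (length(msg)) msg else TRUE
})

#' A simulated scene: observations, truth, DEM, strata and masks
#'
#' @slot config the [SceneConfig-class] the scene was generated from
#' @slot obs data.frame of per-pixel dated observations (pixel, year, doy,
#'   t, sensor, masked, and the six band columns; masked rows carry NA bands)
#' @slot truth per-pixel-per-year truth records in joint response design
#'   classes (plot_id, year, change_process, primary_cover, secondary_covers,
#'   land_use, stratum_id)
#' @slot dem elevation matrix (m)
#' @slot strata integer stratum raster with a `names` attribute
#' @slot masks named list of logical ancillary masks (pixel matrices)
#' @export
setClass("Scene", representation(
  config = "SceneConfig", obs = "data.frame", truth = "data.frame",
  dem = "matrix", strata = "matrix", masks = "list"))

setValidity("Scene", function(object) {
  np <- object@config@n_rows * object@config@n_cols
  if (nrow(object@dem) != object@config@n_rows) return("DEM shape mismatch")
  bands <- as.matrix(object@obs[!object@obs$masked, BAND_NAMES])
  if (length(bands) && (min(bands) < 0 || max(bands) > 1))
    return("reflectances must lie in [0, 1]")
  if (any(!is.na(object@obs[object@obs$masked, BAND_NAMES])))
    return("masked observations must carry no band values")
  TRUE
})

#' Annual medoid composite series with provenance
#'
#' @slot bands numeric array pixel x year x band
#' @slot sensor,doy integer pixel x year provenance matrices
#' @slot interpolated logical pixel x year; TRUE where a gap was filled
#' @slot composite_date numeric pixel x year fractional-year date
#' @slot years integer vector of calendar years
#' @slot dim_grid integer c(n_rows, n_cols)
#' @export
setClass("CompositeSeries", representation(
  bands = "array", sensor = "matrix", doy = "matrix",
  interpolated = "matrix", composite_date = "matrix",
  years = "integer", dim_grid = "integer"))

setValidity("CompositeSeries", function(object) {
  d <- dim(object@bands)
  if (length(d) != 3 || d[3] != length(BAND_NAMES))
    return("bands must be pixel x year x 6 array")
  if (d[2] != length(object@years)) return("year dimension mismatch")
  TRUE
})

#' Piecewise-linear temporal segmentation of one annual series
#'
#' @slot vertices data.frame (year, fitted) with strictly increasing years
#' @slot segments data.frame (start_year, end_year, start_fitted, end_fitted,
#'   slope, magnitude, duration)
#' @slot fitted numeric fitted value per input year
#' @slot years integer input years
#' @slot p_value model p-value from the F screen
#' @slot fallback TRUE when no admissible segmented model existed (or the
#'   series had too few valid years) and a flat fit was returned
#' @export
setClass("LTSegmentation", representation(
  vertices = "data.frame", segments = "data.frame", fitted = "numeric",
  years = "integer", p_value = "numeric", fallback = "logical"))

setValidity("LTSegmentation", function(object) {
  v <- object@vertices$year
  if (length(v) >= 2 && any(diff(v) <= 0))
    return("vertex years must be strictly increasing")
  TRUE
})

#' Harmonic segment set for one pixel (all fitted bands)
#'
#' @slot segments data.frame (t_start, t_end, t_break) in fractional years
#' @slot coefs array 8 x band x segment (intercept, slope, cos/sin 1-3)
#' @slot rmse matrix band x segment
#' @slot bands character band names fitted
#' @export
setClass("CCDCSegmentSet", representation(
  segments = "data.frame", coefs = "array", rmse = "matrix",
  bands = "character"))

setValidity("CCDCSegmentSet", function(object) {
  s <- object@segments
  if (nrow(s) > 1 && any(diff(s$t_start) <= 0))
    return("segments must be time-ordered")
  if (nrow(s) && any(s$t_end < s$t_start)) return("segment ends before start")
  TRUE
})

#' Per-pixel-per-year model predictor cube
#'
#' @slot values numeric array pixel x year x feature
#' @slot registry data.frame describing each feature (name, block, source,
#'   metric); names are unique and stable across runs
#' @slot years integer calendar years
#' @slot complete logical pixel x year; FALSE where any block is missing
#' @export
setClass("FeatureCube", representation(
  values = "array", registry = "data.frame", years = "integer",
  complete = "matrix"))

setValidity("FeatureCube", function(object) {
  if (dim(object@values)[3] != nrow(object@registry))
    return("registry/feature dimension mismatch")
  if (anyDuplicated(object@registry$name)) return("duplicate feature names")
  TRUE
})

#' Per-pixel-per-year class model confidences
#'
#' Confidence is the proportion of random-forest trees voting for a class;
#' per pixel-year the class confidences sum to 1.
#'
#' @slot values numeric array pixel x year x class, in `[0, 1]`
#' @slot classes character class names
#' @slot product "Change", "Land Cover" or "Land Use"
#' @slot years integer calendar years
#' @export
setClass("ConfidenceCube", representation(
  values = "array", classes = "character", product = "character",
  years = "integer"))

setValidity("ConfidenceCube", function(object) {
  v <- object@values
  if (dim(v)[3] != length(object@classes)) return("class dimension mismatch")
  s <- apply(v, c(1, 2), sum)
  ok <- is.na(s) | abs(s - 1) < 1e-6
  if (!all(ok)) return("class confidences must sum to 1 per pixel-year")
  if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
    return("confidences must lie in [0, 1]")
  TRUE
})

#' Assembled annual class maps for one product
#'
#' @slot codes integer matrix pixel x year indexing into `classes`
#' @slot classes character class registry (finest level)
#' @slot product product name
#' @slot level thematic level of `classes`
#' @slot years integer calendar years
#' @export
setClass("ClassMapSeries", representation(
  codes = "matrix", classes = "character", product = "character",
  level = "integer", years = "integer"))

setValidity("ClassMapSeries", function(object) {
  cd <- object@codes
  bad <- !is.na(cd) & (cd < 1L | cd > length(object@classes))
  if (any(bad)) return("codes outside class registry")
  TRUE
})

#' Stratified sample design: counts, proportions and weights
#'
#' @slot design data.frame per stratum: name, proportion, count, weight
#'   (sample share / population share) and inv_weight (its reciprocal,
#'   the inverse-probability weight)
#' @slot total total sample size N
#' @export
setClass("SampleDesign", representation(
  design = "data.frame", total = "integer"))

setValidity("SampleDesign", function(object) {
  d <- object@design
  if (sum(d$count) != object@total) return("counts must sum to total")
  # printed design tables carry rounded proportions; allow rounding slack
  if (abs(sum(d$proportion) - 1) > 0.005)
    return("stratum proportions must sum to 1")
  TRUE
})

#' Design-based weighted accuracy report
#'
#' @slot confusion weighted confusion matrix (truth rows, prediction cols)
#' @slot overall data.frame: overall accuracy, balanced accuracy, kappa and
#'   their standard errors (percent scale for accuracies)
#' @slot by_class data.frame of per-class user's/producer's accuracy and SEs
#' @slot n number of records assessed
#' @export
setClass("ValidationReport", representation(
  confusion = "matrix", overall = "data.frame", by_class = "data.frame",
  n = "integer"))

setValidity("ValidationReport", function(object) {
  oa <- object@overall$overall_accuracy
  if (length(oa) && (oa < 0 || oa > 100)) return("accuracy outside [0, 100]")
  k <- object@overall$kappa
  if (length(k) && !is.na(k) && (k < -1 || k > 1))
    return("kappa outside [-1, 1]")
  TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d x %d pixels, %d-%d, %d obs/yr, noise %.3g\n",
              object@n_rows, object@n_cols, object@year_start,
              object@year_end, object@obs_per_year, object@noise_sd))
  cat(sprintf("  %d event(s), seed %d\n", length(object@events), object@seed))
})

setMethod("show", "Scene", function(object) {
  cfg <- object@config
  cat(sprintf("Scene: %d x %d pixels, %d-%d\n", cfg@n_rows, cfg@n_cols,
              cfg@year_start, cfg@year_end))
  cat(sprintf("  %d observations (%.1f%% masked), %d truth records\n",
              nrow(object@obs), 100 * mean(object@obs$masked),
              nrow(object@truth)))
})

setMethod("show", "CompositeSeries", function(object) {
  cat(sprintf("CompositeSeries: %d pixels x %d years (%d-%d)\n",
              dim(object@bands)[1], length(object@years),
              min(object@years), max(object@years)))
  cat(sprintf("  %.1f%% pixel-years interpolated\n",
              100 * mean(object@interpolated)))
})

setMethod("show", "LTSegmentation", function(object) {
  cat(sprintf("LTSegmentation: %d segment(s) over %d-%d (p = %.3g%s)\n",
              nrow(object@segments), min(object@years), max(object@years),
              object@p_value,
              if (object@fallback) ", fallback fit" else ""))
})

setMethod("show", "CCDCSegmentSet", function(object) {
  cat(sprintf("CCDCSegmentSet: %d segment(s), bands %s\n",
              nrow(object@segments), paste(object@bands, collapse = ", ")))
})

setMethod("show", "FeatureCube", function(object) {
  cat(sprintf("FeatureCube: %d pixels x %d years x %d features\n",
              dim(object@values)[1], dim(object@values)[2],
              dim(object@values)[3]))
  cat("  blocks:", paste(sprintf("%s (%d)",
      names(table(object@registry$block)), table(object@registry$block)),
      collapse = ", "), "\n")
})

setMethod("show", "ConfidenceCube", function(object) {
  cat(sprintf("ConfidenceCube [%s]: %d pixels x %d years x %d classes\n",
              object@product, dim(object@values)[1], dim(object@values)[2],
              length(object@classes)))
})

setMethod("show", "ClassMapSeries", function(object) {
  cat(sprintf("ClassMapSeries [%s, level %d]: %d pixels x %d years\n",
              object@product, object@level, nrow(object@codes),
              length(object@years)))
})

setMethod("show", "SampleDesign", function(object) {
  cat(sprintf("SampleDesign: N = %d over %d strata\n", object@total,
              nrow(object@design)))
  print(object@design, row.names = FALSE)
})

setMethod("show", "ValidationReport", function(object) {
  o <- object@overall
  cat(sprintf(
    "ValidationReport (n = %d): OA %.2f%% (SE %.3f), BA %.2f%% (SE %.3f), kappa %.3f\n",
    object@n, o$overall_accuracy, o$overall_accuracy_se,
    o$balanced_accuracy, o$balanced_accuracy_se, o$kappa))
})
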