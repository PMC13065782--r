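# Harmonic change detection: per-band harmonic LASSO models over all
# unmasked observations, sequential break detection across the breakpoint
# bands, annual predictor extraction at composite dates, and two-run
# feathering.

#' Harmonic change-detection parameters
#'
#' @param breakpointBands bands entering the break score
#' @param minObservations consecutive exceedances required to flag a change
#' @param chiSquareProbability chi-square probability for the change
#'   threshold (df = number of breakpoint bands)
#' @param minNumOfYearsScaler factor on the minimum fitting span for models
#'   started after a break
#' @param lambda LASSO penalty on the reflectance scale; 0 means ordinary
#'   least squares
#' @param maxIterations coordinate-descent iteration cap
#' @return a validated parameter list of class `CCDCParams`
#' @export
ccdcParams <- function(breakpointBands = c("green", "red", "nir", "swir1",
                                           "swir2"),
                       minObservations = 6L, chiSquareProbability = 0.99,
                       minNumOfYearsScaler = 1.33, lambda = 0.002,
                       maxIterations = 10000L) {
  stopifnot(chiSquareProbability > 0, chiSquareProbability < 1,
            lambda >= 0, minObservations >= 1L)
  structure(list(breakpointBands = breakpointBands,
                 minObservations = as.integer(minObservations),
                 chiSquareProbability = chiSquareProbability,
                 minNumOfYearsScaler = minNumOfYearsScaler,
                 lambda = lambda, maxIterations = as.integer(maxIterations)),
            class = "CCDCParams")
}

#' Fit harmonic models with break detection to one pixel's observations
#'
#' Each segment's per-band coefficients (intercept, slope, cosine/sine of
#' harmonics 1-3 cycles/year) minimize the LASSO loss at `lambda` (OLS when
#' 0). A break is declared when `minObservations` consecutive observations
#' exceed the chi-square threshold on the summed squared normalized
#' residuals over the breakpoint bands; a new model starts after the break
#' once a span of `minNumOfYearsScaler` times the minimum fitting span is
#' available.
#'
#' @param t fractional-year observation times
#' @param Y observations matrix (rows = observations, named band columns;
#'   typically the six bands plus NDVI); NA rows are dropped
#' @param params a [ccdcParams()] list
#' @return a [CCDCSegmentSet-class]; with too few observations the segment
#'   table is empty and the `no_model` attribute is set
#' @export
fitCcdc <- function(t, Y, params = ccdcParams()) {
  Y <- as.matrix(Y)
  keep <- !is.na(t) & stats::complete.cases(Y)
  t <- t[keep]; Y <- Y[keep, , drop = FALSE]
  ord <- order(t)
  t <- t[ord]; Y <- Y[ord, , drop = FALSE]
  bands <- colnames(Y)
  empty <- function() {
    out <- new("CCDCSegmentSet",
               segments = data.frame(t_start = numeric(0),
                                     t_end = numeric(0),
                                     t_break = numeric(0)),
               coefs = array(0, c(8, length(bands), 0)),
               rmse = matrix(0, length(bands), 0), bands = bands)
    attr(out, "no_model") <- TRUE
    out
  }
  if (length(t) < 12L || (max(t) - min(t)) < 1) return(empty())
  bp <- match(params$breakpointBands, bands)
  if (anyNA(bp)) stopf("breakpoint bands missing from observation matrix")
  thr <- qchisq(params$chiSquareProbability,
                df = length(params$breakpointBands))
  res <- .ccdc_fit_cpp(t, Y, bp - 1L, params$lambda, params$minObservations,
                       thr, params$minNumOfYearsScaler, params$maxIterations)
  S <- length(res$i_start)
  if (S == 0L) return(empty())
  coefs <- array(0, c(8, length(bands), S),
                 dimnames = list(c("intercept", "slope", "cos1", "sin1",
                                   "cos2", "sin2", "cos3", "sin3"),
                                 bands, NULL))
  rmse <- matrix(0, length(bands), S, dimnames = list(bands, NULL))
  for (s in seq_len(S)) {
    coefs[, , s] <- res$coefs[[s]]
    rmse[, s] <- res$rmse[[s]]
  }
  new("CCDCSegmentSet",
      segments = data.frame(t_start = res$t_start, t_end = res$t_end,
                            t_break = res$t_break),
      coefs = coefs, rmse = rmse, bands = bands)
}

#' Predict the harmonic model of one segment
#'
#' @param segset a [CCDCSegmentSet-class]
#' @param band band name
#' @param t fractional-year times
#' @param segment segment index
#' @return predicted values
#' @export
ccdcPredict <- function(segset, band, t, segment = 1L) {
  X <- .harmonic_design_cpp(as.numeric(t))
  # design column order: 1, t, cos1, sin1, cos2, sin2, cos3, sin3
  as.numeric(X %*% segset@coefs[, band, segment])
}

# segment used for a query date: covering segment; in gaps the next segment
# after the break; at series end the previous segment extended by at most
# 0.3 years; otherwise NA (null pixel-year)
ccdcSegmentFor <- function(segset, date, end_tolerance = 0.3) {
  s <- segments(segset)
  if (nrow(s) == 0L || is.na(date)) return(NA_integer_)
  cover <- which(s$t_start <= date & date <= s$t_end)
  if (length(cover)) return(cover[1])
  nxt <- which(s$t_start > date)
  if (length(nxt)) return(nxt[1])
  last <- nrow(s)
  if (date <= s$t_end[last] + end_tolerance) return(last)
  NA_integer_
}

#' Annual harmonic-model predictors
#'
#' Evaluates each band's harmonic model at the pixel's composite date for
#' each year and returns fitted value, year-over-year fitted difference and
#' the six harmonic coefficients of the segment used. The first year's diff
#' is 0 by convention.
#'
#' @param segset a [CCDCSegmentSet-class]
#' @param years calendar years
#' @param dates fractional-year composite date per year (the fallback median
#'   date should already be substituted for null composite years)
#' @param end_tolerance how far (years) the last segment may extend past its
#'   end before the pixel-year goes null
#' @return matrix years x (band x 8 metrics); rows of years with no eligible
#'   segment are NA
#' @export
ccdcAnnualFeatures <- function(segset, years, dates, end_tolerance = 0.3) {
  bands <- segset@bands
  metrics <- c("fitted", "diff", "cos1", "cos2", "cos3", "sin1", "sin2",
               "sin3")
  cn <- as.vector(t(outer(bands, metrics, paste, sep = "_")))
  out <- matrix(NA_real_, length(years), length(cn),
                dimnames = list(years, paste0("CCDC_", cn)))
  seg <- vapply(dates, function(d) ccdcSegmentFor(segset, d, end_tolerance),
                integer(1))
  fitted <- matrix(NA_real_, length(years), length(bands))
  for (yi in seq_along(years)) {
    if (is.na(seg[yi])) next
    for (bi in seq_along(bands))
      fitted[yi, bi] <- ccdcPredict(segset, bands[bi], dates[yi], seg[yi])
  }
  for (bi in seq_along(bands)) {
    base <- (bi - 1L) * 8L
    dif <- c(0, diff(fitted[, bi]))
    dif[is.na(fitted[, bi])] <- NA_real_
    out[, base + 1L] <- fitted[, bi]
    out[, base + 2L] <- dif
    hc <- segset@coefs[c("cos1", "cos2", "cos3", "sin1", "sin2", "sin3"),
                       bands[bi], , drop = FALSE]
    for (m in seq_len(6))
      out[!is.na(seg), base + 2L + m] <- hc[m, 1, seg[!is.na(seg)]]
  }
  out
}

#' Harmonic predictor stack for a whole scene
#'
#' Fits the harmonic break-detection model per pixel on all unmasked
#' observations (six bands plus NDVI) and evaluates the annual predictors
#' at the pixel's medoid composite dates.
#'
#' @param scene a [Scene-class]
#' @param composites the gap-filled [CompositeSeries-class] supplying
#'   per-year composite dates
#' @param params a [ccdcParams()] list
#' @return list with `features` (pixel x year x 56 array) and `fits` (per
#'   pixel [CCDCSegmentSet-class], when `keep_fits`)
#' @param keep_fits retain per-pixel fits
#' @export
ccdcFeatureStack <- function(scene, composites, params = ccdcParams(),
                             keep_fits = FALSE) {
  obs <- sceneObs(scene)
  years <- composites@years
  np <- dim(compositeBands(composites))[1]
  bandcols <- c(BAND_NAMES, "NDVI")
  obs$NDVI <- normDiff(obs$nir, obs$red)
  keep <- !obs$masked
  obs <- obs[keep, c("pixel", "t", bandcols)]
  split_idx <- split(seq_len(nrow(obs)), obs$pixel)
  cdate <- compositeDates(composites)

  fnames <- NULL
  out <- NULL
  fits <- if (keep_fits) vector("list", np) else NULL
  for (p in seq_len(np)) {
    rows <- split_idx[[as.character(p)]]
    feat <- NULL
    if (!is.null(rows) && length(rows) >= 12L) {
      segset <- fitCcdc(obs$t[rows], as.matrix(obs[rows, bandcols]), params)
      if (keep_fits) fits[[p]] <- segset
      if (!isTRUE(attr(segset, "no_model")))
        feat <- ccdcAnnualFeatures(segset, years, cdate[p, ])
    }
    if (is.null(out) && !is.null(feat)) {
      fnames <- colnames(feat)
      out <- array(NA_real_, c(np, length(years), length(fnames)),
                   dimnames = list(NULL, years, fnames))
    }
    if (!is.null(feat)) out[p, , ] <- feat
  }
  if (is.null(out)) stopf("no pixel had enough observations for a model")
  list(features = out, fits = fits)
}

#' Feather (blend) two overlapping model runs
#'
#' Linearly blends annual predictor values of an older and a newer run
#' across a transition window: before `blend_start` the old run is used
#' unchanged, from `blend_end` + 1 on the new run alone, and within the
#' window the weighted average with weight (year - blend_start) /
#' (blend_end - blend_start) on the new run. With the defaults the weight
#' is 0 in 2013, 1 by 2021, and 2022 onward comes fully from the new run.
#'
#' @param old,new numeric annual series from the two runs
#' @param years calendar years of both series
#' @param blend_start,blend_end transition window
#' @return blended numeric series
#' @export
featherSeries <- function(old, new, years, blend_start = 2013L,
                          blend_end = 2021L) {
  if (blend_end <= blend_start) stopf("blend_end must exceed blend_start")
  stopifnot(length(old) == length(years), length(new) == length(years))
  w <- (years - blend_start) / (blend_end - blend_start)
  w <- pmin(pmax(w, 0), 1)
  (1 - w) * old + w * new
}
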