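# Piecewise-linear temporal segmentation of annual index series and the
# five per-year segmentation predictors (fitted, diff, magnitude, duration,
# slope).

#' Temporal segmentation parameters
#'
#' @param maxSegments maximum number of fitted segments
#' @param spikeThreshold spike damping factor (1 = no damping)
#' @param vertexCountOvershoot extra vertices allowed during the initial
#'   oversearch before pruning back to maxSegments + 1
#' @param preventOneYearRecovery disallow one-year recovery segments
#' @param recoveryThreshold segments recovering (as a fraction of the series
#'   range per year) faster than this are disallowed; 0.25 means full-range
#'   recoveries quicker than 4 years are rejected
#' @param pvalThreshold p-value screen for candidate models
#' @param bestModelProportion among screened models, the one with most
#'   vertices whose p-value is within this proportion of the best is chosen
#' @return a validated parameter list of class `LTParams`
#' @export
ltParams <- function(maxSegments = 9L, spikeThreshold = 0.9,
                     vertexCountOvershoot = 3L,
                     preventOneYearRecovery = FALSE,
                     recoveryThreshold = 0.25, pvalThreshold = 0.05,
                     bestModelProportion = 0.75) {
  stopifnot(maxSegments >= 1L,
            spikeThreshold > 0, spikeThreshold <= 1,
            recoveryThreshold > 0, recoveryThreshold <= 1,
            pvalThreshold > 0, pvalThreshold <= 1,
            bestModelProportion > 0, bestModelProportion <= 1)
  structure(list(maxSegments = as.integer(maxSegments),
                 spikeThreshold = spikeThreshold,
                 vertexCountOvershoot = as.integer(vertexCountOvershoot),
                 preventOneYearRecovery = preventOneYearRecovery,
                 recoveryThreshold = recoveryThreshold,
                 pvalThreshold = pvalThreshold,
                 bestModelProportion = bestModelProportion),
            class = "LTParams")
}

ltFallback <- function(years, values) {
  fit <- rep(mean(values, na.rm = TRUE), length(years))
  segs <- data.frame(start_year = min(years), end_year = max(years),
                     start_fitted = fit[1], end_fitted = fit[1],
                     slope = 0, magnitude = 0,
                     duration = max(years) - min(years))
  new("LTSegmentation",
      vertices = data.frame(year = range(years), fitted = fit[c(1, 1)]),
      segments = segs, fitted = fit, years = as.integer(years),
      p_value = NA_real_, fallback = TRUE)
}

#' Fit a piecewise-linear temporal segmentation
#'
#' Despikes the annual series, oversearches vertices by maximum-residual
#' insertion, prunes to maxSegments + 1 vertices, generates nested candidate
#' models by weakest-vertex removal, disallows candidates containing
#' recovery segments faster than the recovery-rate rule permits, screens by
#' F-test p-value, and picks the admissible model with most vertices whose
#' p-value is within `bestModelProportion` of the best.
#'
#' @param years integer vector of (annual) years
#' @param values numeric series, same length; NAs are dropped
#' @param params an [ltParams()] list
#' @param recovery_sign +1 when vegetation recovery increases the index
#'   (NBR, NDVI, ...), -1 when it decreases it (SWIR, brightness), 0 to
#'   disable the recovery-rate rule
#' @return an [LTSegmentation-class]; series with fewer than 3 valid years
#'   yield a flagged single flat segment
#' @export
fitLandTrendr <- function(years, values, params = ltParams(),
                          recovery_sign = 1L) {
  keep <- !is.na(values)
  years <- as.integer(years[keep]); values <- values[keep]
  if (length(values) < 3L) return(ltFallback(years, values))
  res <- .lt_fit_cpp(as.numeric(years), as.numeric(values),
                     params$maxSegments, params$spikeThreshold,
                     params$vertexCountOvershoot,
                     params$preventOneYearRecovery,
                     params$recoveryThreshold, params$pvalThreshold,
                     params$bestModelProportion, as.integer(recovery_sign))
  vidx <- res$vertex_idx + 1L
  fit <- res$fitted
  vy <- years[vidx]; vf <- fit[vidx]
  k <- length(vidx) - 1L
  segs <- data.frame(start_year = vy[-length(vy)], end_year = vy[-1],
                     start_fitted = vf[-length(vf)], end_fitted = vf[-1])
  segs$duration <- segs$end_year - segs$start_year
  segs$magnitude <- segs$end_fitted - segs$start_fitted
  segs$slope <- segs$magnitude / segs$duration
  new("LTSegmentation",
      vertices = data.frame(year = vy, fitted = vf),
      segments = segs[, c("start_year", "end_year", "start_fitted",
                          "end_fitted", "slope", "magnitude", "duration")],
      fitted = fit, years = years,
      p_value = res$p_value %||% NA_real_, fallback = res$fallback)
}

#' Per-year segmentation predictors
#'
#' For each queried year returns the fitted value, the difference from the
#' containing segment's start-vertex fitted value, and the containing
#' segment's magnitude, duration and slope. A vertex year belongs to the
#' segment it starts; the final year belongs to the last segment.
#'
#' @param seg an [LTSegmentation-class]
#' @param years years to query (must lie within the segmentation span)
#' @return data.frame with columns fitted, diff, magnitude, duration, slope
#' @export
ltAnnualFeatures <- function(seg, years = seg@years) {
  v <- vertices(seg); s <- segments(seg)
  if (any(years < min(v$year) | years > max(v$year)))
    stopf("queried year outside segmentation span")
  si <- pmin(findInterval(years, v$year), nrow(s))
  fitted <- s$start_fitted[si] + s$slope[si] * (years - s$start_year[si])
  data.frame(fitted = fitted, diff = fitted - s$start_fitted[si],
             magnitude = s$magnitude[si], duration = s$duration[si],
             slope = s$slope[si])
}

#' Segmentation predictor stack for a whole scene
#'
#' Fits the segmentation independently per index series (14 series per
#' pixel) and extracts the five annual predictors for each.
#'
#' @param stack pixel x year x index array from [indexStack()]
#' @param params an [ltParams()] list
#' @param indices which index layers to fit (default: all present)
#' @return list with `features` (pixel x year x (index x 5) array) and
#'   `segmentations` kept only when `keep_fits = TRUE`
#' @param keep_fits retain per-pixel [LTSegmentation-class] objects: TRUE
#'   for all indices, or a character vector of index names (e.g. "NBR" for
#'   loss-stratum derivation)
#' @export
ltFeatureStack <- function(stack, params = ltParams(),
                           indices = dimnames(stack)[[3]],
                           keep_fits = FALSE) {
  np <- dim(stack)[1]; ny <- dim(stack)[2]
  years <- as.integer(dimnames(stack)[[2]])
  metrics <- c("fitted", "diff", "magnitude", "duration", "slope")
  fnames <- as.vector(t(outer(indices, metrics, paste, sep = "_")))
  fnames <- paste0("LT_", fnames)
  out <- array(NA_real_, c(np, ny, length(fnames)),
               dimnames = list(NULL, years, fnames))
  fits <- list()
  for (ii in seq_along(indices)) {
    idx <- indices[ii]
    sign <- INDEX_RECOVERY_SIGN[[idx]] %||% 0L
    keep <- isTRUE(keep_fits) ||
      (is.character(keep_fits) && idx %in% keep_fits)
    pfits <- if (keep) vector("list", np) else NULL
    base <- (ii - 1L) * 5L
    for (p in seq_len(np)) {
      if (keep) {
        seg <- fitLandTrendr(years, stack[p, , idx], params, sign)
        pfits[[p]] <- seg
        f <- ltAnnualFeatures(seg, years)
        for (m in seq_len(5))
          out[p, , base + m] <- f[[metrics[m]]]
      } else {
        # lean path: raw fit, features computed from plain vectors
        vals <- stack[p, , idx]
        ok <- !is.na(vals)
        if (sum(ok) < 3L) {
          mu <- mean(vals, na.rm = TRUE)
          out[p, , base + 1L] <- mu
          out[p, , base + 2L] <- 0
          out[p, , base + 3L] <- 0
          out[p, , base + 4L] <- max(years) - min(years)
          out[p, , base + 5L] <- 0
          next
        }
        yrs <- years[ok]
        res <- .lt_fit_cpp(as.numeric(yrs), as.numeric(vals[ok]),
                           params$maxSegments, params$spikeThreshold,
                           params$vertexCountOvershoot,
                           params$preventOneYearRecovery,
                           params$recoveryThreshold, params$pvalThreshold,
                           params$bestModelProportion, as.integer(sign))
        vidx <- res$vertex_idx + 1L
        vy <- yrs[vidx]; vf <- res$fitted[vidx]
        nseg <- length(vidx) - 1L
        si <- pmin(findInterval(years, vy), nseg)
        si[si < 1L] <- 1L
        sl <- (vf[si + 1L] - vf[si]) / (vy[si + 1L] - vy[si])
        fitted <- vf[si] + sl * (years - vy[si])
        out[p, , base + 1L] <- fitted
        out[p, , base + 2L] <- fitted - vf[si]
        out[p, , base + 3L] <- vf[si + 1L] - vf[si]
        out[p, , base + 4L] <- vy[si + 1L] - vy[si]
        out[p, , base + 5L] <- sl
      }
    }
    if (keep) fits[[idx]] <- pfits
  }
  list(features = out, segmentations = fits)
}
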