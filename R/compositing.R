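# Annual medoid compositing with provenance, gap interpolation, and
# spectral feature computation.

#' Geometric medoid composite of one observation window
#'
#' Returns the single unmasked observation minimizing the summed squared
#' deviation from the per-band medians over the green, red, NIR, SWIR1 and
#' SWIR2 bands. All band values of the composite come from that one
#' acquisition; ties are broken to the earliest day of year.
#'
#' @param values numeric matrix (observations x 6 bands, columns named after
#'   [BAND_NAMES]); masked observations should be excluded or carry NA rows
#' @param doy integer day of year per observation
#' @param sensor integer sensor code per observation
#' @return list with `bands` (named length-6 vector), `sensor`, `doy` and
#'   `index` of the chosen observation, or NULL when no unmasked
#'   observation exists (a null composite, not an error)
#' @export
medoidComposite <- function(values, doy, sensor = rep(NA_integer_,
                                                      length(doy))) {
  values <- as.matrix(values)
  keep <- stats::complete.cases(values)
  if (!any(keep)) return(NULL)
  idx <- which(keep)
  ord <- idx[order(doy[idx])]
  V <- values[ord, MEDOID_BANDS, drop = FALSE]
  m <- apply(V, 2, median)
  d <- colSums((t(V) - m)^2)
  pick <- ord[which.min(d)] # which.min returns first minimum: earliest DOY
  list(bands = stats::setNames(as.numeric(values[pick, BAND_NAMES]),
                               BAND_NAMES),
       sensor = sensor[pick], doy = as.integer(doy[pick]), index = pick)
}

#' Build annual medoid composites for a whole scene
#'
#' @param scene a [Scene-class]
#' @param window optional day-of-year window overriding the scene's
#'   compositing window
#' @return a [CompositeSeries-class] (not yet gap-filled; see
#'   [interpolateMissing()])
#' @export
annualComposites <- function(scene, window = NULL) {
  cfg <- sceneConfig(scene)
  window <- window %||% cfg@window
  obs <- sceneObs(scene)
  years <- cfg@year_start:cfg@year_end
  np <- cfg@n_rows * cfg@n_cols
  ny <- length(years)

  inw <- obs$doy >= window[1] & obs$doy <= window[2]
  obs <- obs[inw, , drop = FALSE]
  yi <- match(obs$year, years)
  grp <- (obs$pixel - 1L) * ny + yi
  ord <- order(grp, obs$t)
  obs <- obs[ord, , drop = FALSE]
  grp <- grp[ord]

  V <- as.matrix(obs[, MEDOID_BANDS])
  V[is.na(V)] <- 0 # masked rows are skipped via the mask flag
  pick <- .medoid_groups_cpp(V, as.integer(grp), obs$masked,
                             as.integer(np * ny))

  bands <- array(NA_real_, c(np, ny, 6),
                 dimnames = list(NULL, years, BAND_NAMES))
  sensor <- matrix(NA_integer_, np, ny)
  doy <- matrix(NA_integer_, np, ny)
  cdate <- matrix(NA_real_, np, ny)
  hit <- which(pick > 0L)
  if (length(hit)) {
    rows <- pick[hit]
    px <- ((hit - 1L) %/% ny) + 1L
    yy <- ((hit - 1L) %% ny) + 1L
    for (b in seq_len(6))
      bands[cbind(px, yy, b)] <- obs[[BAND_NAMES[b]]][rows]
    sensor[cbind(px, yy)] <- obs$sensor[rows]
    doy[cbind(px, yy)] <- obs$doy[rows]
    cdate[cbind(px, yy)] <- obs$t[rows]
  }
  new("CompositeSeries", bands = bands, sensor = sensor, doy = doy,
      interpolated = matrix(FALSE, np, ny), composite_date = cdate,
      years = as.integer(years), dim_grid = c(cfg@n_rows, cfg@n_cols))
}

#' Fill missing composite years by linear interpolation
#'
#' Null years between valid years are filled per band by linear
#' interpolation in year; leading/trailing nulls take the nearest valid
#' year's values. Filled years are flagged interpolated, and their
#' composite date falls back to the pixel's median composite date
#' (fractional part) applied to the missing year. Pixels with no valid
#' year at all are left null and recorded in the `rejected` attribute.
#'
#' @param composites a [CompositeSeries-class]
#' @return the gap-filled [CompositeSeries-class]
#' @export
interpolateMissing <- function(composites) {
  bands <- compositeBands(composites)
  np <- dim(bands)[1]; ny <- dim(bands)[2]
  years <- composites@years
  cdate <- composites@composite_date
  interp <- composites@interpolated
  rejected <- integer(0)
  for (p in seq_len(np)) {
    valid <- which(!is.na(bands[p, , 1]))
    if (length(valid) == 0L) { rejected <- c(rejected, p); next }
    gaps <- setdiff(seq_len(ny), valid)
    if (length(gaps) == 0L) next
    if (length(valid) == 1L) {
      for (b in seq_len(6)) bands[p, gaps, b] <- bands[p, valid, b]
    } else {
      for (b in seq_len(6))
        bands[p, gaps, b] <- approx(years[valid], bands[p, valid, b],
                                    xout = years[gaps], rule = 2)$y
    }
    interp[p, gaps] <- TRUE
    fallback_frac <- median(cdate[p, valid] - years[valid])
    cdate[p, gaps] <- years[gaps] + fallback_frac
  }
  if (length(rejected))
    message(sprintf("interpolateMissing: %d pixel(s) with no valid year rejected",
                    length(rejected)))
  out <- new("CompositeSeries", bands = bands, sensor = composites@sensor,
             doy = composites@doy, interpolated = interp,
             composite_date = cdate, years = years,
             dim_grid = composites@dim_grid)
  attr(out, "rejected") <- rejected
  out
}
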