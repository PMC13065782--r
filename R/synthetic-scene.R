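# Synthetic-scene generation: raster scenes of dated multiband observation
# time series with known annual truth labels, strata, DEM and ancillary
# masks. Pixel ids are linear indices into an n_rows x n_cols matrix
# (column-major, 1-based), so a pixel vector reshapes to a raster with
# matrix(x, n_rows, n_cols).

# land-use zone archetypes used by the default layout
ZONE_TABLE <- data.frame(
  code = 1:7,
  name = c("forest", "shrubland", "grassland", "agriculture", "developed",
           "water", "wetland"),
  cover = c("Tree", "Shrub", "Grass/Forb/Herbaceous", "Grass/Forb/Herbaceous",
            "Barren or Impervious", "Water", "Grass/Forb/Herbaceous"),
  land_use = c("Forest", "Rangeland or Pasture", "Rangeland or Pasture",
               "Agriculture", "Developed", "Other", "Non-Forest Wetland"),
  seas_scale = c(1, 1, 1.5, 4, 0.3, 0.2, 1.2),
  stringsAsFactors = FALSE)

# zone base spectra; agriculture gets a NIR boost, developed a man-made
# signature, wetland a grass/water mixture
zoneSpectrum <- function(zone_code) {
  z <- ZONE_TABLE[zone_code, ]
  s <- BASE_SPECTRA[z$cover, ]
  if (z$name == "agriculture") s["nir"] <- s["nir"] + 0.06
  if (z$name == "developed")
    s <- c(0.130, 0.150, 0.160, 0.240, 0.260, 0.240)
  if (z$name == "wetland")
    s <- 0.65 * BASE_SPECTRA["Grass/Forb/Herbaceous", ] +
      0.35 * BASE_SPECTRA["Water", ]
  stats::setNames(as.numeric(s), BAND_NAMES)
}

#' Construct a scene configuration
#'
#' @param n_rows,n_cols grid size in pixels
#' @param year_start,year_end calendar year span
#' @param obs_per_year observations per pixel per year (default 15)
#' @param noise_sd observation noise SD in reflectance units (default 0.01)
#' @param seasonal_amplitude named per-band first-harmonic amplitude
#' @param events list of event descriptors (`pixels`, `year`, `kind`,
#'   `magnitude`, optional `duration`, `recovery_years`)
#' @param window day-of-year range observation dates are drawn from
#' @param mask_prob per-observation cloud/shadow masking probability
#' @param zones integer land-use zone matrix, or NULL for the default
#'   column-banded layout
#' @param seed integer seed; identical seeds give identical scenes
#' @return a [SceneConfig-class]
#' @export
SceneConfig <- function(n_rows, n_cols, year_start, year_end,
                        obs_per_year = 15L, noise_sd = 0.01,
                        seasonal_amplitude = NULL, events = list(),
                        window = c(152L, 273L), mask_prob = 0.1,
                        zones = NULL, seed = 1L) {
  if (is.null(seasonal_amplitude))
    seasonal_amplitude <- c(blue = 0.002, green = 0.004, red = 0.005,
                            nir = 0.030, swir1 = 0.015, swir2 = 0.010)
  if (is.null(zones)) zones <- defaultZones(n_rows, n_cols)
  new("SceneConfig", n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      year_start = as.integer(year_start), year_end = as.integer(year_end),
      obs_per_year = as.integer(obs_per_year), noise_sd = noise_sd,
      seasonal_amplitude = seasonal_amplitude, events = events,
      window = as.integer(window), mask_prob = mask_prob,
      zones = zones, seed = as.integer(seed))
}

# default landscape: vertical zone bands
defaultZones <- function(n_rows, n_cols) {
  prop <- c(forest = 0.40, shrubland = 0.12, grassland = 0.15,
            agriculture = 0.12, developed = 0.08, water = 0.06,
            wetland = 0.07)
  prop <- prop / sum(prop)
  k <- length(prop)
  if (n_cols < k) stopf("grid too narrow for the default zone layout")
  cnt <- pmax(floor(prop * n_cols), 1L)
  while (sum(cnt) > n_cols) cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
  rem <- prop * n_cols - cnt
  while (sum(cnt) < n_cols) {
    i <- which.max(rem)
    cnt[i] <- cnt[i] + 1L
    rem[i] <- -Inf
  }
  zcol <- rep(seq_len(k), cnt)
  matrix(rep(zcol, each = n_rows), n_rows, n_cols)
}

#' Pixel ids of a rectangular patch
#' @param rows,cols row/column index ranges
#' @param n_rows number of rows of the scene grid
#' @return integer pixel ids (column-major linear indices)
#' @export
patchPixels <- function(rows, cols, n_rows) {
  as.integer(outer(rows, (cols - 1L) * n_rows, "+"))
}

#' Demo scene configuration with well-separated events
#'
#' Builds a [SceneConfig-class] over the default zone layout with a harvest,
#' a fire, a structural-decline ramp, a growth patch and a flooding event,
#' all placed in compatible zones and separated in space and time.
#'
#' @inheritParams SceneConfig
#' @param ... passed through to [SceneConfig()]
#' @export
demoSceneConfig <- function(n_rows = 32L, n_cols = 32L, year_start = 1994L,
                            year_end = 2023L, seed = 1L, ...) {
  zones <- defaultZones(n_rows, n_cols)
  zcols <- function(code) which(apply(zones == code, 2, any))
  fc <- zcols(1L); sc <- zcols(2L); wc <- zcols(7L)
  third <- max(1L, n_rows %/% 3)
  ey <- function(k) min(year_start + k, year_end) # clamp to short spans
  events <- list(
    list(pixels = patchPixels(1:third, fc[seq_len(ceiling(length(fc) / 2))],
                              n_rows),
         year = ey(6L), kind = "harvest", magnitude = 0.45,
         recovery_years = 12L),
    list(pixels = patchPixels((third + 1):(2 * third),
                              fc[seq_len(ceiling(length(fc) / 2))], n_rows),
         year = ey(14L), kind = "fire", magnitude = 0.35,
         recovery_years = 12L),
    list(pixels = patchPixels((2 * third + 1):n_rows,
                              fc[seq_len(ceiling(length(fc) / 2))], n_rows),
         year = ey(16L), kind = "decline", magnitude = 0.20,
         duration = 8L),
    list(pixels = patchPixels(1:third, sc, n_rows),
         year = ey(4L), kind = "growth", magnitude = 0.30,
         duration = 10L),
    list(pixels = patchPixels(1:third, wc[1], n_rows),
         year = ey(10L), kind = "hydrology", magnitude = 1,
         duration = 6L))
  SceneConfig(n_rows, n_cols, year_start, year_end, events = events,
              zones = zones, seed = seed, ...)
}

# solve the disturbance mixing fraction so the NBR drop of the mixed
# spectrum equals `magnitude`; capped at full replacement
solveDisturbFraction <- function(mature, target, magnitude) {
  nbr <- function(s) (s["nir"] - s["swir2"]) / (s["nir"] + s["swir2"])
  drop <- function(d) nbr(mature) - nbr((1 - d) * mature + d * target)
  if (drop(1) <= magnitude) return(1)
  stats::uniroot(function(d) drop(d) - magnitude, c(0, 1),
                 tol = 1e-10)$root
}

# annual disturbance fraction trajectory for one event over `years`;
# also returns per-year change-process labels implied by the event
eventTrajectory <- function(ev, years) {
  d <- numeric(length(years))
  proc <- rep(NA_character_, length(years))
  y0 <- ev$year
  i0 <- match(y0, years)
  if (ev$kind %in% c("fire", "harvest")) {
    R <- ev$recovery_years %||% 10L
    rel <- years - y0
    act <- rel >= 0 & rel <= R
    d[act] <- (1 - rel[act] / R)
    proc[rel == 0] <- if (ev$kind == "fire") "Fire" else "Harvest"
    proc[rel > 0 & rel <= R] <- "Growth/Recovery"
  } else if (ev$kind == "decline") {
    D <- ev$duration %||% 8L
    rel <- years - y0
    ramp <- rel >= 0 & rel < D
    d[ramp] <- (rel[ramp] + 1) / D
    d[rel >= D] <- 1
    proc[ramp] <- "Structural Decline"
  } else if (ev$kind == "growth") {
    D <- ev$duration %||% 10L
    rel <- years - y0
    d[rel <= 0] <- 1
    gr <- rel > 0 & rel <= D
    d[gr] <- 1 - rel[gr] / D
    proc[gr] <- "Growth/Recovery"
  } else if (ev$kind == "hydrology") {
    D <- ev$duration %||% 5L
    rel <- years - y0
    flood <- rel >= 0 & rel < D
    d[flood] <- 1
    proc[rel == 0 | rel == D] <- "Hydrology"
  }
  list(d = d, proc = proc)
}

# succession ladder from barren up to the mature cover of a pixel
successionLadder <- function(mature_cover) {
  full <- c("Barren or Impervious", "Grass/Forb/Herbaceous", "Shrub", "Tree")
  top <- unname(SUCCESSION[mature_cover])
  if (is.na(top)) top <- 1L
  full[seq_len(top)]
}

#' Generate a synthetic scene
#'
#' Simulates per-pixel dated multiband reflectance observations with
#' cloud/shadow masks, annual truth records in joint response design
#' classes, a DEM, a stratum raster and ancillary masks. Spectral dynamics
#' are a mixture model: each pixel's spectrum is interpolated between its
#' mature zone spectrum and a disturbance endpoint (barren, or water for
#' flooding) by an annual disturbance fraction driven by the event table;
#' fire/harvest events are scaled so the NBR drop in the event year equals
#' the configured magnitude. Within-year seasonality is a first-harmonic
#' sinusoid per band; observation noise is Gaussian.
#'
#' @param config a [SceneConfig-class]
#' @return a [Scene-class]
#' @export
generateScene <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    nr <- config@n_rows; nc <- config@n_cols
    np <- nr * nc
    years <- config@year_start:config@year_end
    ny <- length(years)
    opy <- config@obs_per_year
    zones <- config@zones
    zvec <- as.integer(zones)

    # mature spectrum per pixel: zone spectrum + fixed pixel-level offset
    zspec <- t(vapply(ZONE_TABLE$code, zoneSpectrum, numeric(6)))
    mature <- zspec[zvec, , drop = FALSE] +
      matrix(rnorm(np * 6, 0, 0.004), np, 6)
    mature <- pmin(pmax(mature, 0.001), 0.999)
    colnames(mature) <- BAND_NAMES

    # annual disturbance fraction and process label per pixel-year
    dfrac <- matrix(0, np, ny)
    target <- matrix(rep(BASE_SPECTRA["Barren or Impervious", ], each = np),
                     np, 6)
    proc <- matrix(NA_character_, np, ny)
    for (ev in config@events) {
      traj <- eventTrajectory(ev, years)
      px <- ev$pixels
      if (any(px < 1 | px > np)) stopf("event pixels outside the grid")
      scale <- if (ev$kind == "hydrology") rep(1, length(px)) else
        vapply(px, function(p)
          solveDisturbFraction(mature[p, ], BASE_SPECTRA["Barren or Impervious", ],
                               ev$magnitude), numeric(1))
      for (k in seq_along(px)) {
        p <- px[k]
        dk <- traj$d * scale[k]
        sel <- dk > dfrac[p, ]
        dfrac[p, sel] <- dk[sel]
        if (ev$kind == "hydrology")
          target[p, ] <- BASE_SPECTRA["Water", ]
        upd <- !is.na(traj$proc)
        proc[p, upd] <- traj$proc[upd]
      }
    }
    proc[is.na(proc)] <- "Stable"

    # observation dates: common acquisition calendar per year
    w <- config@window
    doys <- matrix(0L, ny, opy)
    for (yi in seq_len(ny)) {
      pool <- w[1]:w[2]
      doys[yi, ] <- sort(sample(pool, opy, replace = opy > length(pool)))
    }
    sensor_seq <- SENSOR_CODES[((seq_len(ny * opy) - 1L) %%
                                  length(SENSOR_CODES)) + 1L]

    # assemble observation table (pixel fastest, then obs, then year)
    n_obs <- np * ny * opy
    pixel <- rep(seq_len(np), times = ny * opy)
    year_i <- rep(seq_len(ny), each = np * opy)
    obs_i <- rep(rep(seq_len(opy), each = np), times = ny)
    doy <- doys[cbind(year_i, obs_i)]
    sens <- sensor_seq[(year_i - 1L) * opy + obs_i]
    tfrac <- fractionalYear(years[year_i], doy)

    d_obs <- dfrac[cbind(pixel, year_i)]
    seas <- cos(2 * pi * (doy - 200) / 365)
    amp <- config@seasonal_amplitude
    zs <- ZONE_TABLE$seas_scale[zvec][pixel] * (1 - d_obs)

    vals <- matrix(0, n_obs, 6)
    for (b in seq_len(6)) {
      base <- (1 - d_obs) * mature[pixel, b] + d_obs * target[pixel, b]
      vals[, b] <- base + amp[b] * zs * seas
    }
    if (config@noise_sd > 0)
      vals <- vals + matrix(rnorm(n_obs * 6, 0, config@noise_sd), n_obs, 6)
    vals <- pmin(pmax(vals, 0), 1)
    colnames(vals) <- BAND_NAMES

    masked <- runif(n_obs) < config@mask_prob
    vals[masked, ] <- NA_real_

    obs <- data.frame(pixel = pixel, year = years[year_i], doy = doy,
                      t = tfrac, sensor = sens, masked = masked,
                      vals, stringsAsFactors = FALSE)
    obs <- obs[order(obs$pixel, obs$t), ]
    rownames(obs) <- NULL

    # truth records
    ladders <- lapply(ZONE_TABLE$cover, successionLadder)
    zuse <- ZONE_TABLE$land_use[zvec]
    zname <- ZONE_TABLE$name[zvec]
    primary <- matrix("", np, ny)
    secondary <- matrix("", np, ny)
    for (p in seq_len(np)) {
      lad <- ladders[[zvec[p]]]
      Lm <- length(lad)
      dp <- dfrac[p, ]
      if (all(dp == 0)) {
        primary[p, ] <- ZONE_TABLE$cover[zvec[p]]
        next
      }
      if (any(target[p, BAND_NAMES == "nir"] ==
              BASE_SPECTRA["Water", "nir"])) { # flooded pixel
        primary[p, ] <- ifelse(dp >= 0.5, "Water", ZONE_TABLE$cover[zvec[p]])
        next
      }
      lc <- 1 + (1 - dp) * (Lm - 1)
      lev <- pmin(floor(lc + 1e-9), Lm)
      primary[p, ] <- lad[lev]
      fracpart <- lc - lev
      sec <- lev < Lm & fracpart >= 0.5 & dp > 0
      secondary[p, sec] <- lad[pmin(lev[sec] + 1L, Lm)]
    }

    truth <- data.frame(
      plot_id = rep(seq_len(np), times = ny),
      year = rep(years, each = np),
      change_process = as.vector(proc),
      primary_cover = as.vector(primary),
      secondary_covers = as.vector(secondary),
      land_use = rep(zuse, times = ny),
      stratum_id = rep(zname, times = ny),
      stringsAsFactors = FALSE)
    # water and snow never carry secondaries
    truth$secondary_covers[
      truth$primary_cover %in% c("Water", "Snow or Ice")] <- ""

    # DEM: smooth analytic relief plus gentle correlated noise
    rowi <- matrix(seq_len(nr), nr, nc)
    coli <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    dem <- 500 + 300 * sin(pi * rowi / nr) * cos(2 * pi * coli / nc) +
      matrix(rnorm(np, 0, 1.5), nr, nc)

    strata <- zones
    attr(strata, "names_table") <- stats::setNames(ZONE_TABLE$name,
                                                   ZONE_TABLE$code)
    masks <- list(built = zones == 5L, water = zones == 6L,
                  cropland = zones == 4L)

    new("Scene", config = config, obs = obs, truth = truth, dem = dem,
        strata = strata, masks = masks)
  })
}
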