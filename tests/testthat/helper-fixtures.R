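# Shared fixtures and independent oracles. Everything here is built in
# code at test time; the oracles deliberately re-derive results by brute
# force, independent of the package's implementation paths.

.fixtures <- new.env(parent = emptyenv())

# small demo scene shared across tests (lazily built once)
tinyScene <- function() {
  if (is.null(.fixtures$scene))
    .fixtures$scene <- generateScene(
      demoSceneConfig(10, 10, 1996, 2015, seed = 42L))
  .fixtures$scene
}

tinyComposites <- function() {
  if (is.null(.fixtures$comp))
    .fixtures$comp <- interpolateMissing(annualComposites(tinyScene()))
  .fixtures$comp
}

# a quiet single-zone (all forest) configuration with no events
quietConfig <- function(n = 4L, years = c(2000L, 2014L), noise_sd = 0,
                        seasonal = 0, seed = 7L, ...) {
  SceneConfig(n, n, years[1], years[2], noise_sd = noise_sd,
              seasonal_amplitude = stats::setNames(rep(seasonal, 6),
                                                   BAND_NAMES),
              zones = matrix(1L, n, n), mask_prob = 0, seed = seed, ...)
}

# annual per-pixel mean of unmasked observed band values (noise-free
# scenes give the exact annual spectrum)
annualObsMean <- function(scene, pixel, band) {
  obs <- sceneObs(scene)
  o <- obs[obs$pixel == pixel & !obs$masked, ]
  tapply(o[[band]], o$year, mean)
}

# --- medoid oracle: brute force over all candidates --------------------
medoidOracle <- function(values, doy) {
  keep <- stats::complete.cases(values)
  if (!any(keep)) return(NULL)
  V <- values[keep, MEDOID_BANDS, drop = FALSE]
  meds <- apply(V, 2, function(col) {
    s <- sort(col)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else mean(s[n / 2 + 0:1])
  })
  d <- apply(V, 1, function(r) sum((r - meds)^2))
  cand <- which(d == min(d))
  idx <- which(keep)[cand]
  idx[which.min(doy[idx])]
}

# --- continuous piecewise-linear least squares (oracle fit) ------------
pwlOracleFit <- function(x, y, vyears) {
  X <- cbind(1, x)
  for (k in vyears[-c(1, length(vyears))]) X <- cbind(X, pmax(0, x - k))
  beta <- qr.solve(qr(X), y)
  as.numeric(X %*% beta)
}

# recovery-rate rule, re-derived
pwlViolates <- function(x, fit, vyears, recoveryThreshold, sign, rng) {
  vi <- match(vyears, x)
  for (s in seq_len(length(vi) - 1)) {
    dv <- fit[vi[s + 1]] - fit[vi[s]]
    dur <- x[vi[s + 1]] - x[vi[s]]
    if (dur <= 0 || dv * sign <= 0) next
    if ((abs(dv) / rng) / dur > recoveryThreshold + 1e-12) return(TRUE)
  }
  FALSE
}

# exhaustive vertex-subset enumeration oracle for short series: fits every
# subset of interior vertices up to maxSegments, applies the recovery rule
# and the p-value screens, and returns the selected model
ltEnumOracle <- function(years, values, params = ltParams(),
                         recovery_sign = 1L) {
  x <- as.numeric(years); y <- values
  n <- length(y)
  rng <- max(y) - min(y)
  interior <- 2:(n - 1)
  best <- list()
  for (k in 0:(min(params$maxSegments, n - 1) - 1)) { # interior vertex count
    combs <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(interior, k), 2)
    bestSse <- Inf; bestFit <- NULL; bestV <- NULL
    for (cm in combs) {
      vy <- x[c(1, cm, n)]
      fit <- pwlOracleFit(x, y, vy)
      if (pwlViolates(x, fit, vy, params$recoveryThreshold, recovery_sign,
                      rng)) next
      sse <- sum((y - fit)^2)
      if (sse < bestSse) { bestSse <- sse; bestFit <- fit; bestV <- vy }
    }
    if (is.null(bestFit)) next
    npar <- k + 2
    df2 <- n - npar
    sst <- sum((y - mean(y))^2)
    p <- if (bestSse <= 1e-18) 0 else if (df2 <= 0 || sst <= bestSse) 1 else
      stats::pf(((sst - bestSse) / (npar - 1)) / (bestSse / df2),
                npar - 1, df2, lower.tail = FALSE)
    best[[length(best) + 1]] <- list(v = bestV, fit = bestFit, sse = bestSse,
                                     p = p, nseg = k + 1)
  }
  pv <- vapply(best, `[[`, numeric(1), "p")
  pmin <- min(pv)
  cutoff <- if (pmin > params$pvalThreshold) pmin else
    pmin / params$bestModelProportion
  ok <- which(pv <= cutoff + 1e-15)
  best[[ok[which.max(vapply(best[ok], `[[`, numeric(1), "nseg"))]]]
}

# textbook unweighted confusion-matrix metrics, re-derived directly
textbookMetrics <- function(truth, pred) {
  classes <- sort(unique(c(truth, pred)))
  C <- table(factor(truth, classes), factor(pred, classes))
  oa <- sum(diag(C)) / sum(C)
  pa <- diag(C) / rowSums(C)
  ua <- diag(C) / colSums(C)
  pe <- sum(rowSums(C) * colSums(C)) / sum(C)^2
  list(oa = 100 * oa, pa = 100 * pa, ua = 100 * ua,
       ba = 100 * mean(pa[rowSums(C) > 0], na.rm = TRUE),
       kappa = (oa - pe) / (1 - pe))
}

# build an LTSegmentation by hand from vertex years/values (for feature
# extraction tests)
manualSegmentation <- function(vy, vf, years = min(vy):max(vy)) {
  fit <- stats::approx(vy, vf, xout = years)$y
  segs <- data.frame(start_year = vy[-length(vy)], end_year = vy[-1],
                     start_fitted = vf[-length(vf)], end_fitted = vf[-1])
  segs$duration <- segs$end_year - segs$start_year
  segs$magnitude <- segs$end_fitted - segs$start_fitted
  segs$slope <- segs$magnitude / segs$duration
  new("LTSegmentation", vertices = data.frame(year = vy, fitted = vf),
      segments = segs, fitted = fit, years = as.integer(years),
      p_value = 0, fallback = FALSE)
}

# simulated harmonic observation series for CCDC tests
harmonicSeries <- function(years = 2000:2015, obs_per_year = 12,
                           mean = 0.5, amp_cos = 0.2, amp_sin = -0.1,
                           slope = 0, noise_sd = 0, seed = NULL,
                           step_at = NULL, step_size = 0) {
  if (!is.null(seed)) set.seed(seed)
  t <- sort(rep(years, each = obs_per_year) +
              runif(length(years) * obs_per_year))
  y <- mean + slope * (t - min(t)) + amp_cos * cos(2 * pi * t) +
    amp_sin * sin(2 * pi * t)
  if (!is.null(step_at)) y <- y + step_size * (t >= step_at)
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  list(t = t, y = y)
}

# five-band observation matrix built from one base series (bands offset so
# values stay in a reflectance-like range)
harmonicBands <- function(series, n_bands = 5) {
  Y <- sapply(seq_len(n_bands), function(b) series$y * 0.5 + 0.05 * b)
  colnames(Y) <- c("green", "red", "nir", "swir1", "swir2")[seq_len(n_bands)]
  Y
}
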