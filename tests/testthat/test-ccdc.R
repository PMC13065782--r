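# Harmonic LASSO change detection: coefficient recovery, break detection,
# LASSO solver against glmnet, gap rules and feathering.

test_that("coordinate-descent LASSO matches glmnet on random problems", {
  skip_if_not_installed("glmnet")
  set.seed(9)
  for (rep in 1:5) {
    n <- 200; p <- 7
    X <- cbind(1, matrix(rnorm(n * p), n, p))
    beta <- c(0.5, rnorm(p) * c(1, 1, 0, 0, 1, 0, 0))
    y <- as.numeric(X %*% beta) + rnorm(n, 0, 0.1)
    lam <- 0.02
    ours <- .lasso_cd_cpp(X, y, lam, 10000L)
    g <- glmnet::glmnet(X[, -1], y, lambda = lam, standardize = TRUE,
                        thresh = 1e-12)
    ref <- as.numeric(c(g$a0, as.matrix(g$beta)))
    expect_equal(ours, ref, tolerance = 1e-3)
  }
})

test_that("a noise-free annual sinusoid is recovered to machine tolerance", {
  s <- harmonicSeries(seed = 21)
  Y <- harmonicBands(s)
  fit <- fitCcdc(s$t, Y, ccdcParams(lambda = 0))
  expect_equal(nrow(segments(fit)), 1)           # no breaks
  expect_true(is.na(segments(fit)$t_break))
  co <- fit@coefs[, "green", 1]
  expect_equal(unname(co["cos1"]), 0.2 * 0.5, tolerance = 1e-8)
  expect_equal(unname(co["sin1"]), -0.1 * 0.5, tolerance = 1e-8)
  expect_equal(unname(co[c("cos2", "sin2", "cos3", "sin3")]), rep(0, 4),
               tolerance = 1e-8)
  # predicted series equals truth within 1e-8
  pred <- ccdcPredict(fit, "green", s$t, 1)
  expect_equal(pred, Y[, "green"], tolerance = 1e-8)
})

test_that("a constant noisy series gives a flat model with rmse near the noise", {
  set.seed(4)
  t <- sort(rep(2000:2015, each = 12) + runif(192))
  Y <- matrix(0.4, 192, 5) + matrix(rnorm(192 * 5, 0, 0.01), 192)
  colnames(Y) <- c("green", "red", "nir", "swir1", "swir2")
  fit <- fitCcdc(t, Y, ccdcParams(lambda = 0))
  expect_equal(nrow(segments(fit)), 1)
  expect_equal(unname(fit@coefs["intercept", "green", 1]) +
                 mean(2000:2016) * unname(fit@coefs["slope", "green", 1]),
               0.4, tolerance = 0.01)
  expect_equal(unname(fit@rmse["green", 1]), 0.01, tolerance = 0.05)
})

test_that("an injected step produces one break near the true time", {
  s <- harmonicSeries(noise_sd = 0.01, seed = 31, step_at = 2008.0,
                      step_size = 0.2) # 10 x noise on the base series
  Y <- harmonicBands(s)
  fit <- fitCcdc(s$t, Y, ccdcParams())
  segs <- segments(fit)
  expect_equal(sum(!is.na(segs$t_break)), 1)
  expect_lt(abs(segs$t_break[1] - 2008.0), 0.25)
})

test_that("event-free noisy series yield zero breaks", {
  for (seed in 1:5) {
    s <- harmonicSeries(noise_sd = 0.01, seed = 100 + seed)
    fit <- fitCcdc(s$t, harmonicBands(s), ccdcParams())
    expect_true(all(is.na(segments(fit)$t_break)))
  }
})

test_that("too few observations give a flagged no-model result", {
  fit <- fitCcdc(2000 + (1:8) / 10,
                 matrix(0.3, 8, 5,
                        dimnames = list(NULL, c("green", "red", "nir",
                                                "swir1", "swir2"))))
  expect_true(isTRUE(attr(fit, "no_model")))
  expect_equal(nrow(segments(fit)), 0)
})

test_that("annual features obey the gap and end-extension rules", {
  # hand-built segment set: one trend-only segment per band
  coefs <- array(0, c(8, 1, 2), dimnames = list(
    c("intercept", "slope", "cos1", "sin1", "cos2", "sin2", "cos3", "sin3"),
    "nir", NULL))
  coefs["intercept", 1, 1] <- -39.8; coefs["slope", 1, 1] <- 0.02
  coefs["intercept", 1, 2] <- 0.3
  segset <- new("CCDCSegmentSet",
                segments = data.frame(t_start = c(2000.5, 2008.5),
                                      t_end = c(2005.0, 2012.0),
                                      t_break = c(2005.4, NA)),
                coefs = coefs, rmse = matrix(0.01, 1, 2), bands = "nir")
  # pure trend, annual spacing: diff equals slope x 1 year
  f <- ccdcAnnualFeatures(segset, 2001:2004, 2001:2004 + 0.5)
  expect_equal(unname(diff(f[, "CCDC_nir_fitted"])), rep(0.02, 3),
               tolerance = 1e-10)
  expect_equal(unname(f[2:4, "CCDC_nir_diff"]), rep(0.02, 3),
               tolerance = 1e-10)
  # a date in the inter-segment gap uses the next segment
  g <- ccdcAnnualFeatures(segset, 2006L, 2006.5)
  expect_equal(unname(g[1, "CCDC_nir_fitted"]), 0.3)
  # 0.2 years past the last segment end: previous segment still used
  h <- ccdcAnnualFeatures(segset, 2012L, 2012.2)
  expect_equal(unname(h[1, "CCDC_nir_fitted"]), 0.3)
  # 0.4 years past: null pixel-year
  i <- ccdcAnnualFeatures(segset, 2012L, 2012.4)
  expect_true(all(is.na(i)))
})

test_that("feathering blends linearly between the runs", {
  years <- 2010:2023
  old <- seq_along(years) * 0.01 + 0.3
  new <- rev(seq_along(years)) * 0.01 + 0.5
  out <- featherSeries(old, new, years)
  expect_equal(out[years == 2013], old[years == 2013])   # weight 0
  expect_equal(out[years == 2022], new[years == 2022])   # fully new
  expect_equal(out[years == 2023], new[years == 2023])
  expect_equal(out[years == 2017],
               (old[years == 2017] + new[years == 2017]) / 2)
  expect_true(all(out >= pmin(old, new) - 1e-12 &
                    out <= pmax(old, new) + 1e-12))
  # blend weight is non-decreasing in year
  w <- (out - old) / (new - old)
  expect_true(all(diff(w) >= -1e-12))
  expect_error(featherSeries(old, new, years, 2020, 2020), "exceed")
})
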