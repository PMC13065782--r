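# Medoid compositing, gap interpolation, spectral features.

test_that("a single unmasked observation is its own composite", {
  v <- matrix(runif(6), 1, dimnames = list(NULL, BAND_NAMES))
  out <- medoidComposite(v, doy = 180L, sensor = 8L)
  expect_equal(out$bands, setNames(as.numeric(v), BAND_NAMES))
  expect_identical(out$sensor, 8L)
  expect_identical(out$doy, 180L)
})

test_that("medoid equals the brute-force oracle and ties go to earliest day", {
  set.seed(1)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    v <- matrix(runif(n * 6), n, dimnames = list(NULL, BAND_NAMES))
    doy <- sort(sample(150:270, n))
    out <- medoidComposite(v, doy)
    expect_identical(out$index, medoidOracle(v, doy))
  }
  # all observations identical: earliest day of year wins
  v <- matrix(rep(runif(6), each = 4), 4, dimnames = list(NULL, BAND_NAMES))
  out <- medoidComposite(v, doy = c(200L, 160L, 220L, 180L))
  expect_identical(out$doy, 160L)
})

test_that("null composites arise from all-masked windows, not errors", {
  v <- matrix(NA_real_, 3, 6, dimnames = list(NULL, BAND_NAMES))
  expect_null(medoidComposite(v, doy = c(150L, 160L, 170L)))
})

test_that("scene-level compositing matches the per-window operation", {
  sc <- tinyScene()
  comp <- annualComposites(sc)
  obs <- sceneObs(sc)
  years <- sceneConfig(sc)@year_start:sceneConfig(sc)@year_end
  for (p in c(1, 37, 93)) {
    for (y in c(years[1], years[10])) {
      o <- obs[obs$pixel == p & obs$year == y & !obs$masked, ]
      ref <- medoidComposite(as.matrix(o[, BAND_NAMES]), o$doy, o$sensor)
      yi <- match(y, years)
      expect_equal(as.numeric(compositeBands(comp)[p, yi, ]),
                   as.numeric(ref$bands))
      expect_identical(comp@doy[p, yi], ref$doy)
      expect_identical(comp@sensor[p, yi], ref$sensor)
    }
  }
  # non-interpolated provenance stays within the compositing window
  w <- sceneConfig(sc)@window
  expect_true(all(comp@doy >= w[1] & comp@doy <= w[2], na.rm = TRUE))
})

test_that("gap interpolation is linear in year with correct flags", {
  bands <- array(NA_real_, c(1, 3, 6))
  bands[1, 1, ] <- 0.2
  bands[1, 3, ] <- 0.4
  comp <- new("CompositeSeries", bands = bands,
              sensor = matrix(c(5L, NA, 7L), 1),
              doy = matrix(c(180L, NA, 200L), 1),
              interpolated = matrix(FALSE, 1, 3),
              composite_date = matrix(c(2004.49, NA, 2006.55), 1),
              years = 2004:2006, dim_grid = c(1L, 1L))
  filled <- interpolateMissing(comp)
  expect_equal(as.numeric(compositeBands(filled)[1, 2, ]), rep(0.3, 6))
  expect_identical(interpolatedFlags(filled)[1, ], c(FALSE, TRUE, FALSE))
  # fallback composite date: missing year + pixel's median fractional date
  expect_equal(compositeDates(filled)[1, 2], 2005 + median(c(0.49, 0.55)))

  # no gaps: series unchanged, zero flags
  full <- comp
  full@bands[1, 2, ] <- 0.3
  full@sensor[1, 2] <- 9L; full@doy[1, 2] <- 190L
  full@composite_date[1, 2] <- 2005.5
  out <- interpolateMissing(full)
  expect_identical(compositeBands(out), full@bands)
  expect_false(any(interpolatedFlags(out)))

  # gap between equal neighbours reproduces the value
  eq <- comp
  eq@bands[1, 3, ] <- 0.2
  expect_equal(as.numeric(compositeBands(interpolateMissing(eq))[1, 2, ]),
               rep(0.2, 6))
})

test_that("interpolated flags mark exactly the null years", {
  comp <- annualComposites(tinyScene())
  filled <- interpolateMissing(comp)
  was_null <- is.na(compositeBands(comp)[, , 1])
  has_any <- apply(!was_null, 1, any)
  expect_equal(interpolatedFlags(filled)[has_any, ],
               was_null[has_any, ], ignore_attr = TRUE)
})

test_that("spectral features follow their definitions", {
  b <- c(blue = 0.05, green = 0.1, red = 0.3, nir = 0.3, swir1 = 0.2,
         swir2 = 0.25)
  f <- spectralFeatures(b)
  expect_equal(f[1, "NDVI"], 0)                      # NIR == red
  expect_equal(f[1, "NBR"], (0.3 - 0.25) / 0.55)
  b2 <- c(blue = 0.1, green = 0.2, red = 0.1, nir = 0.5, swir1 = 0.2,
          swir2 = 0.25)
  f2 <- spectralFeatures(b2)
  expect_equal(f2[1, "NBR"], (0.5 - 0.25) / 0.75)    # = 1/3
  expect_equal(f2[1, "NBR"], 1 / 3)
  # equal brightness and greenness give a 45 degree angle
  cf <- rbind(TCB = rep(1, 6), TCG = rep(1, 6), TCW = rep(0, 6))
  colnames(cf) <- BAND_NAMES
  f3 <- spectralFeatures(b2, coefs = cf)
  expect_equal(unname(f3[1, "TCA"]), 45)
  # zero denominator gives a null feature
  f4 <- spectralFeatures(c(blue = 0, green = 0, red = 0, nir = 0,
                           swir1 = 0, swir2 = 0))
  expect_true(is.na(f4[1, "NDVI"]))
})

test_that("normalized-difference indices stay in [-1,1] for positive bands", {
  set.seed(2)
  b <- matrix(runif(600, 0.01, 1), 100, 6,
              dimnames = list(NULL, BAND_NAMES))
  f <- spectralFeatures(b)
  nd <- f[, c("NDVI", "NBR", "NDMI", "NDSI")]
  expect_true(all(nd >= -1 & nd <= 1))
})

test_that("feature computation is pure per pixel (reordering commutes)", {
  comp <- tinyComposites()
  st <- indexStack(comp)
  perm <- sample(dim(st)[1])
  comp2 <- comp
  comp2@bands <- comp@bands[perm, , , drop = FALSE]
  st2 <- indexStack(comp2)
  expect_equal(st2, st[perm, , , drop = FALSE], ignore_attr = TRUE)
})
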