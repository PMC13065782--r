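# Piecewise-linear temporal segmentation: model-class identities, the
# recovery-rate rule against the enumeration oracle, and the annual
# predictors.

test_that("a constant series yields one flat segment fitting exactly", {
  y <- rep(0.6, 15)
  seg <- fitLandTrendr(2000:2014, y)
  expect_equal(nrow(segments(seg)), 1)
  expect_equal(segments(seg)$slope, 0, tolerance = 1e-10)
  expect_equal(fittedSeries(seg), y, tolerance = 1e-10)
})

test_that("noise-free piecewise-linear series are recovered exactly", {
  yrs <- 1994:2013
  vy <- c(1994, 2001, 2005, 2013)
  vf <- c(0.7, 0.7, 0.3, 0.55)
  y <- approx(vy, vf, xout = yrs)$y
  seg <- fitLandTrendr(yrs, y, recovery_sign = 0L)
  expect_equal(vertices(seg)$year, vy)
  expect_equal(vertices(seg)$fitted, vf, tolerance = 1e-8)
  expect_equal(fittedSeries(seg), y, tolerance = 1e-8)
  # a richer shape, still within the segment budget
  vy2 <- c(1994, 1997, 2000, 2004, 2008, 2013)
  vf2 <- c(0.2, 0.5, 0.45, 0.8, 0.3, 0.35)
  y2 <- approx(vy2, vf2, xout = yrs)$y
  seg2 <- fitLandTrendr(yrs, y2, recovery_sign = 0L)
  expect_equal(vertices(seg2)$year, vy2)
  expect_equal(fittedSeries(seg2), y2, tolerance = 1e-8)
})

test_that("two-year full-range recoveries are rejected by the rate rule", {
  yrs <- 1994:2013
  y <- c(rep(0.8, 9), rep(0.2, 6), 0.5, rep(0.8, 4)) # recovery 2008->2010
  seg <- fitLandTrendr(yrs, y, ltParams(), recovery_sign = 1L)
  rng <- diff(range(y))
  segs <- segments(seg)
  rate <- (abs(segs$magnitude) / rng) / segs$duration
  recovering <- segs$magnitude > 0
  expect_true(all(rate[recovering] <= 0.25 + 1e-9))
  # enumeration oracle: the optimal admissible model also avoids it, and
  # the heuristic search lands close to (never below) that optimum
  oracle <- ltEnumOracle(yrs, y, ltParams(maxSegments = 4), 1L)
  seg4 <- fitLandTrendr(yrs, y, ltParams(maxSegments = 4), 1L)
  sse4 <- sum((y - fittedSeries(seg4))^2)
  expect_gte(sse4, oracle$sse - 1e-9)
  expect_lte(sse4, 1.5 * oracle$sse)
  expect_false(pwlViolates(as.numeric(yrs), oracle$fit, oracle$v, 0.25,
                           1L, rng))
  # with the rule disabled the 2-year recovery is captured instead
  seg_off <- fitLandTrendr(yrs, y, ltParams(), recovery_sign = 0L)
  expect_true(any((segments(seg_off)$magnitude /
                     rng / segments(seg_off)$duration) > 0.25))
})

test_that("segment magnitudes telescope and the fit passes its vertices", {
  sc <- tinyScene()
  st <- indexStack(tinyComposites())
  yrs <- as.integer(dimnames(st)[[2]])
  for (p in c(3, 41, 77)) {
    seg <- fitLandTrendr(yrs, st[p, , "NBR"])
    v <- vertices(seg)
    expect_equal(fittedSeries(seg)[match(v$year, yrs)], v$fitted,
                 tolerance = 1e-9)
    expect_equal(sum(segments(seg)$magnitude),
                 fittedSeries(seg)[length(yrs)] - fittedSeries(seg)[1],
                 tolerance = 1e-9)
  }
})

test_that("segmentation is equivariant to constant shifts", {
  set.seed(5)
  yrs <- 1994:2013
  y <- approx(c(1994, 2003, 2013), c(0.3, 0.7, 0.5), xout = yrs)$y +
    rnorm(20, 0, 0.01)
  a <- fitLandTrendr(yrs, y, recovery_sign = 0L)
  b <- fitLandTrendr(yrs, y + 0.2, recovery_sign = 0L)
  expect_identical(vertices(a)$year, vertices(b)$year)
  expect_equal(fittedSeries(b), fittedSeries(a) + 0.2, tolerance = 1e-8)
})

test_that("annual predictors follow the containing segment", {
  seg <- manualSegmentation(c(2000, 2004, 2010), c(0.8, 0.4, 0.4))
  f <- ltAnnualFeatures(seg, 2002) # two years into the 0.8 -> 0.4 segment
  expect_equal(f$fitted, 0.6)
  expect_equal(f$slope, -0.1)
  expect_equal(f$magnitude, -0.4)
  expect_equal(f$duration, 4)
  expect_equal(f$diff, -0.2)
  # a vertex year belongs to the segment it starts: diff is 0 there
  f0 <- ltAnnualFeatures(seg, c(2000, 2004))
  expect_equal(f0$diff, c(0, 0))
  expect_equal(f0$magnitude, c(-0.4, 0))   # 2004 starts the flat segment
  # flat segment: magnitude and slope 0, duration = its length
  f1 <- ltAnnualFeatures(seg, 2007)
  expect_equal(f1$magnitude, 0)
  expect_equal(f1$slope, 0)
  expect_equal(f1$duration, 6)
  # the final year belongs to the last segment
  fend <- ltAnnualFeatures(seg, 2010)
  expect_equal(fend$duration, 6)
  expect_error(ltAnnualFeatures(seg, 2011), "outside")
})

test_that("short series fall back to a flagged flat fit", {
  seg <- fitLandTrendr(2000:2001, c(0.2, 0.4))
  expect_true(seg@fallback)
  expect_equal(nrow(segments(seg)), 1)
})
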