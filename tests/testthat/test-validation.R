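# Grouped folds and design-based weighted accuracy metrics.

test_that("grouped folds never split a plot and balance strata", {
  strat_of <- rep(c("a", "b", "c"), each = 10)
  plots <- data.frame(plot_id = rep(1:30, each = 4),
                      stratum = strat_of[rep(1:30, each = 4)])
  folds <- groupedStratifiedKfold(plots, k = 5, seed = 1)
  expect_length(folds, 30)
  # records of a plot inherit a single fold by construction
  rec_folds <- folds[as.character(plots$plot_id)]
  expect_true(all(tapply(rec_folds, plots$plot_id,
                         function(v) length(unique(v))) == 1))
  # strata spread evenly across folds
  per <- table(folds, plots$stratum[match(names(folds), plots$plot_id)])
  expect_lte(max(per) - min(per), 1)
  # one plot per fold when k equals the number of plots
  p10 <- data.frame(plot_id = 1:10, stratum = "s")
  f10 <- groupedStratifiedKfold(p10, k = 10, seed = 2)
  expect_identical(sort(as.integer(table(f10))), rep(1L, 10))
  expect_error(groupedStratifiedKfold(p10, k = 11), "exceeds")
})

test_that("fold sizes in records differ by at most the largest plot", {
  set.seed(3)
  plots <- data.frame(plot_id = 1:40, stratum = sample(c("x", "y"), 40, TRUE))
  recs <- plots[rep(1:40, times = sample(1:6, 40, TRUE)), ]
  folds <- groupedStratifiedKfold(recs, k = 5, seed = 4)
  sizes <- table(folds[as.character(recs$plot_id)])
  maxplot <- max(table(recs$plot_id))
  # each fold holds 8 plots; record counts differ by at most 8 x max size,
  # and in practice by far less - assert the construction bound
  expect_lte(max(sizes) - min(sizes), 8 * maxplot)
})

test_that("a hand-tallied confusion matrix reproduces the textbook numbers", {
  # confusion [[40,10],[20,30]] with unit weights
  truth <- c(rep("A", 50), rep("B", 50))
  pred <- c(rep("A", 40), rep("B", 10), rep("A", 20), rep("B", 30))
  r <- weightedAccuracyMetrics(truth, pred)
  expect_equal(reportOverall(r)$overall_accuracy, 70)
  bc <- reportByClass(r)
  expect_equal(bc$producers_accuracy, c(80, 60))
  expect_equal(bc$users_accuracy, c(400 / 6, 75), tolerance = 1e-9)
  expect_equal(reportOverall(r)$balanced_accuracy, 70)
  expect_equal(reportConfusion(r), matrix(c(40, 20, 10, 30), 2,
               dimnames = list(truth = c("A", "B"),
                               predicted = c("A", "B"))))
})

test_that("perfect prediction gives 100/100/1 with zero standard errors", {
  truth <- sample(letters[1:4], 200, TRUE)
  w <- runif(200, 0.5, 3)
  r <- weightedAccuracyMetrics(truth, truth, weights = w)
  o <- reportOverall(r)
  expect_equal(o$overall_accuracy, 100)
  expect_equal(o$balanced_accuracy, 100)
  expect_equal(o$kappa, 1)
  expect_equal(o$overall_accuracy_se, 0)
  expect_equal(o$balanced_accuracy_se, 0)
})

test_that("unit weights reproduce textbook formulas on random confusions", {
  set.seed(17)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    n <- sample(50:300, 1)
    truth <- sample(letters[1:k], n, TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(letters[1:k], n, TRUE))
    r <- weightedAccuracyMetrics(truth, pred)
    tb <- textbookMetrics(truth, pred)
    expect_equal(reportOverall(r)$overall_accuracy, tb$oa)
    expect_equal(reportOverall(r)$kappa, tb$kappa)
    expect_equal(reportOverall(r)$balanced_accuracy, tb$ba)
    bc <- reportByClass(r)
    expect_equal(bc$producers_accuracy, unname(tb$pa))
    expect_equal(bc$users_accuracy, unname(tb$ua))
  }
})

test_that("metrics are invariant under joint class relabelling", {
  set.seed(23)
  truth <- sample(c("A", "B", "C"), 150, TRUE)
  pred <- ifelse(runif(150) < 0.7, truth, sample(c("A", "B", "C"), 150, TRUE))
  w <- runif(150, 0.2, 2)
  r1 <- weightedAccuracyMetrics(truth, pred, w)
  relab <- c(A = "Z", B = "Q", C = "M")
  r2 <- weightedAccuracyMetrics(relab[truth], relab[pred], w)
  expect_equal(reportOverall(r1)$overall_accuracy,
               reportOverall(r2)$overall_accuracy)
  expect_equal(reportOverall(r1)$kappa, reportOverall(r2)$kappa)
  expect_equal(sort(reportByClass(r1)$producers_accuracy),
               sort(reportByClass(r2)$producers_accuracy))
})

test_that("standard errors shrink like one over root n", {
  set.seed(29)
  ns <- c(250, 500, 1000, 2000, 4000)
  se <- sapply(ns, function(n) {
    reps <- replicate(5, {
      truth <- rep("A", n)
      pred <- ifelse(runif(n) < 0.8, "A", "B")
      reportOverall(weightedAccuracyMetrics(truth, pred))$overall_accuracy_se
    })
    mean(reps)
  })
  slope <- coef(lm(log(se) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("stratified weighting shifts the estimate toward the population", {
  # two strata, stratum b heavily oversampled and much less accurate
  truth <- c(rep("A", 80), rep("A", 80))
  pred <- c(rep("A", 76), rep("B", 4),          # stratum a: 95% correct
            rep("A", 40), rep("B", 40))         # stratum b: 50% correct
  stratum <- rep(c("a", "b"), each = 80)
  P <- c(a = 0.9, b = 0.1)
  w <- ifelse(stratum == "a", P["a"] / 0.5, P["b"] / 0.5)
  r <- weightedAccuracyMetrics(truth, pred, w, stratum = stratum,
                               proportions = P)
  expect_equal(reportOverall(r)$overall_accuracy,
               100 * (0.9 * 0.95 + 0.1 * 0.5), tolerance = 1e-9)
  expect_gt(reportOverall(r)$overall_accuracy_se, 0)
})

test_that("confidence-interval half-widths follow 1.96 x SE", {
  expect_equal(round(ciHalfWidth(0.04), 3), 0.078)
  expect_equal(ciHalfWidth(1), qnorm(0.975))
})

test_that("a class with zero truth mass has undefined producer accuracy", {
  r <- weightedAccuracyMetrics(c("A", "A"), c("A", "B"))
  bc <- reportByClass(r)
  expect_true(is.na(bc$producers_accuracy[bc$class == "B"]))
})
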