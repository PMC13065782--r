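# Predictor pruning, grouped selection and tuning, vote confidences and
# F1 thresholds.

test_that("correlation pruning drops the later member of duplicated pairs", {
  set.seed(3)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  X <- cbind(X, a2 = X[, "a"]) # exact duplicate, later registry index
  expect_identical(pruneCorrelated(X), c("a", "b", "c"))
  # orthogonal features are all retained
  Xo <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, letters[1:5]))
  expect_identical(pruneCorrelated(Xo), letters[1:5])
  # constant features have undefined correlation, treated as 0
  Xc <- cbind(Xo, konst = 1)
  expect_true("konst" %in% pruneCorrelated(Xc))
})

test_that("three mutually correlated features collapse to the first", {
  set.seed(8)
  base <- rnorm(400)
  X <- cbind(f1 = base, f2 = base + rnorm(400, 0, 0.05),
             f3 = base + rnorm(400, 0, 0.05))
  stopifnot(min(abs(cor(X))) > 0.95)
  kept <- pruneCorrelated(X)
  # greedy oracle over registry order: f2 drops against f1, f3 against f1
  expect_identical(kept, "f1")
})

test_that("grouped RFE recovers the informative features", {
  set.seed(12)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- factor(ifelse(x1 + x2 + rnorm(n, 0, 0.3) > 0, "A", "B"))
  noise <- matrix(rnorm(n * 20), n, 20,
                  dimnames = list(NULL, paste0("n", 1:20)))
  X <- cbind(inf1 = x1, inf2 = x2, noise)
  groups <- rep(1:100, each = 5)
  sel <- selectFeaturesRFE(X, y, groups, folds = 5, num_trees = 80,
                           seed = 5)
  expect_true(all(c("inf1", "inf2") %in% sel))
  # single feature input is retained
  one <- selectFeaturesRFE(X[, "inf1", drop = FALSE], y, groups,
                           folds = 5, num_trees = 50, seed = 5)
  expect_identical(as.character(one), "inf1")
})

test_that("grid search returns feasible argmax with the stated tie-breaks", {
  set.seed(13)
  n <- 200
  y <- factor(rep(c("A", "B"), each = n / 2))
  x <- cbind(f1 = ifelse(y == "A", 1, -1) + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 3), n, 3,
                    dimnames = list(NULL, paste0("f", 2:4))))
  # wide margin: every forest separates the classes perfectly
  groups <- rep(1:40, each = 5)
  grid1 <- data.frame(num_trees = 60L, min_node = 5L, mtry = NA)
  best1 <- tuneHyperparams(x, y, groups, grid1, folds = 5, seed = 2)
  expect_equal(best1$num_trees, 60L)
  # all four cells reach accuracy 1; ties go to fewer trees, larger leaf
  grid <- expand.grid(num_trees = c(50L, 100L), min_node = c(1L, 5L),
                      mtry = NA)
  best <- tuneHyperparams(x, y, groups, grid, folds = 5, seed = 2)
  expect_equal(attr(best, "scores"), rep(1, 4), tolerance = 1e-12)
  expect_equal(best$num_trees, 50L)
  expect_equal(best$min_node, 5L)
  # infeasible mtry is skipped with a warning
  gridbad <- data.frame(num_trees = 50L, min_node = 1L, mtry = 99L)
  expect_warning(expect_error(tuneHyperparams(x, y, groups, gridbad,
                                              folds = 5, seed = 2)),
                 "infeasible")
})

test_that("confidence is the proportion of trees voting for each class", {
  set.seed(20)
  n <- 150
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(ifelse(X[, 1] + rnorm(n, 0, 0.8) > 0, "Gain", "Stable"))
  rf <- trainConfidenceModel(X, y, num_trees = 51, seed = 1)
  conf <- predictConfidence(rf, X[1:20, ])
  # per-tree tally oracle
  ind <- predict(rf, as.data.frame(X[1:20, ]), predict.all = TRUE,
                 num.threads = 1)$predictions
  tally <- t(apply(ind, 1, function(r)
    table(factor(rf$forest$levels[r], levels(y))) / length(r)))
  expect_equal(unname(conf), unname(tally), tolerance = 1e-12)
  expect_equal(rowSums(conf), rep(1, 20), tolerance = 1e-12)
})

test_that("single-class training yields confidence 1 everywhere", {
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  rf <- trainConfidenceModel(X, rep("Stable", 20), num_trees = 25, seed = 1)
  conf <- predictConfidence(rf, X)
  expect_true(all(conf[, "Stable"] == 1))
})

test_that("prediction is invariant to feature column order", {
  set.seed(22)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(ifelse(X[, 2] > 0, "A", "B"))
  rf <- trainConfidenceModel(X, y, num_trees = 40, seed = 9)
  c1 <- predictConfidence(rf, X[1:10, ])
  c2 <- predictConfidence(rf, X[1:10, c("c", "a", "b")])
  expect_equal(c1, c2)
})

test_that("F1 threshold selection matches a brute-force scan", {
  # separable case: lowest optimal grid threshold is 0.11
  conf <- cbind(Gain = c(rep(0.9, 10), rep(0.1, 10)))
  truth <- c(rep("Gain", 10), rep("Stable", 10))
  th <- selectChangeThresholds(conf, truth)
  expect_equal(unname(th["Gain"]), 0.11)
  # all-positive truth: threshold 0 gives precision = recall = 1
  th0 <- selectChangeThresholds(cbind(Gain = runif(10, 0.2, 0.9)),
                                rep("Gain", 10))
  expect_equal(unname(th0["Gain"]), 0)
  # random case against an independent scan
  set.seed(30)
  conf <- cbind(Loss = runif(200))
  truth <- ifelse(conf[, 1] + rnorm(200, 0, 0.3) > 0.5, "Loss", "Stable")
  th <- selectChangeThresholds(conf, truth)
  grid <- seq(0, 1, 0.01)
  f1 <- sapply(grid, function(g) {
    tp <- sum(conf[, 1] >= g & truth == "Loss")
    fp <- sum(conf[, 1] >= g & truth != "Loss")
    fn <- sum(conf[, 1] < g & truth == "Loss")
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  })
  expect_equal(unname(th["Loss"]), grid[which.max(f1)])
  # absent class is flagged
  expect_warning(thna <- selectChangeThresholds(conf, rep("Stable", 200),
                                                classes = "Loss"),
                 "absent")
  expect_true(is.na(thna["Loss"]))
})
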