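# Supervised modeling: predictor pruning, grouped recursive feature
# elimination, grouped grid search, random-forest confidence prediction
# (proportion of trees voting per class) and F1-optimal change thresholds.

#' Drop highly correlated predictors
#'
#' Two-step filter: first, for every pair with |r| above `r_max` the member
#' with the later registry index is dropped; second, any remaining variable
#' whose mean absolute correlation across all remaining pairs exceeds
#' `r_max` is dropped. Constant predictors have undefined correlations,
#' treated as 0.
#'
#' @param X numeric matrix or data.frame of predictors (columns in registry
#'   order)
#' @param r_max correlation threshold (default 0.95)
#' @return character vector of retained column names
#' @export
pruneCorrelated <- function(X, r_max = 0.95) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) return(colnames(X))
  C <- suppressWarnings(abs(cor(X)))
  C[is.na(C)] <- 0
  diag(C) <- 0
  p <- ncol(X)
  keep <- rep(TRUE, p)
  for (j in 2:p) {
    if (any(keep[1:(j - 1)] & C[1:(j - 1), j] > r_max)) keep[j] <- FALSE
  }
  idx <- which(keep)
  if (length(idx) > 1L) {
    Cm <- C[idx, idx, drop = FALSE]
    meanAbs <- rowSums(Cm) / (length(idx) - 1L)
    idx <- idx[meanAbs <= r_max]
  }
  colnames(X)[idx]
}

# grouped CV accuracy of a random forest on the given feature set
groupedCvAccuracy <- function(X, y, groups, folds, num_trees = 100L,
                              min_node = 5L, mtry = NULL, seed = NULL) {
  y <- factor(y)
  acc <- numeric(max(folds))
  n_used <- 0L
  for (f in sort(unique(folds))) {
    test <- folds[groups] == f
    if (!any(test) || all(test)) next
    m <- trainConfidenceModel(X[!test, , drop = FALSE], y[!test],
                              num_trees = num_trees, min_node = min_node,
                              mtry = mtry, seed = childSeed(seed, f))
    pred <- predictClasses(m, X[test, , drop = FALSE])
    acc[f] <- mean(pred == y[test])
    n_used <- n_used + 1L
  }
  sum(acc) / max(n_used, 1L)
}

#' Recursive feature elimination with grouped cross-validation
#'
#' Repeatedly drops the least important fraction of predictors (random
#' forest impurity importance on the full training set) and scores each
#' candidate set by grouped k-fold cross-validated overall accuracy; the
#' set with the highest accuracy is retained (ties to the smaller set).
#' When a class is missing from some fold's training split, folds are
#' rebuilt stratifying plots by their majority class (logged).
#'
#' @param X predictor matrix (named columns)
#' @param y class labels
#' @param groups plot ids (records of one plot never split across folds)
#' @param folds number of folds (default 5)
#' @param step fraction of features dropped per iteration
#' @param num_trees trees per forest during scoring
#' @param seed RNG seed
#' @return character vector: the selected feature names, with the CV
#'   accuracy trace in the `trace` attribute
#' @export
selectFeaturesRFE <- function(X, y, groups, folds = 5L, step = 0.1,
                              num_trees = 100L, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  groups <- as.character(groups)
  plots <- unique(groups)
  fold_of <- groupedStratifiedKfold(
    data.frame(plot_id = plots, stratum = "all"), k = folds, seed = seed)
  # ensure every training split sees every class; else stratify by class
  plot_class <- vapply(split(as.character(y), groups), function(v)
    names(sort(table(v), decreasing = TRUE))[1], character(1))
  bad <- any(vapply(seq_len(folds), function(f) {
    tr <- fold_of[groups] != f
    nlevels(droplevels(y[tr])) < nlevels(droplevels(y))
  }, logical(1)))
  if (bad) {
    message("selectFeaturesRFE: class missing from a fold; ",
            "stratifying groups by majority class")
    fold_of <- groupedStratifiedKfold(
      data.frame(plot_id = plots, stratum = plot_class[plots]),
      k = folds, seed = seed)
  }
  current <- colnames(X)
  trace <- list()
  best <- NULL; best_acc <- -Inf
  repeat {
    acc <- groupedCvAccuracy(X[, current, drop = FALSE], y, groups, fold_of,
                             num_trees = num_trees, seed = seed)
    trace[[length(trace) + 1L]] <- data.frame(n = length(current), acc = acc)
    if (acc > best_acc + 1e-12 ||
        (abs(acc - best_acc) <= 1e-12 && length(current) < length(best))) {
      best <- current; best_acc <- acc
    }
    if (length(current) <= 1L) break
    rf <- trainConfidenceModel(X[, current, drop = FALSE], y,
                               num_trees = num_trees,
                               seed = childSeed(seed, length(current)))
    imp <- rf$variable.importance
    ndrop <- max(1L, ceiling(step * length(current)))
    current <- current[order(imp, decreasing = TRUE)]
    current <- sort(match(current[seq_len(length(current) - ndrop)],
                          colnames(X)))
    current <- colnames(X)[current]
  }
  structure(best, trace = do.call(rbind, trace), accuracy = best_acc)
}

#' Grouped grid search over random-forest hyperparameters
#'
#' @param X,y,groups as in [selectFeaturesRFE()]
#' @param grid data.frame with columns num_trees, min_node, mtry (NA mtry =
#'   default)
#' @param folds number of folds (default 10)
#' @param seed RNG seed
#' @return the best grid row (ties broken to fewer trees, then larger
#'   minimum leaf), with the per-row accuracies in attribute `scores`
#' @export
tuneHyperparams <- function(X, y, groups, grid, folds = 10L, seed = 1L) {
  if (nrow(grid) == 0L) stopf("empty hyperparameter grid")
  X <- as.matrix(X)
  groups <- as.character(groups)
  plots <- unique(groups)
  fold_of <- groupedStratifiedKfold(
    data.frame(plot_id = plots, stratum = "all"), k = folds, seed = seed)
  scores <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    mtry <- grid$mtry[g]
    if (!is.na(mtry) && mtry > ncol(X)) {
      warning(sprintf("grid row %d infeasible (mtry %d > %d features); skipped",
                      g, mtry, ncol(X)))
      next
    }
    scores[g] <- groupedCvAccuracy(
      X, y, groups, fold_of, num_trees = grid$num_trees[g],
      min_node = grid$min_node[g],
      mtry = if (is.na(mtry)) NULL else mtry, seed = seed)
  }
  if (all(is.na(scores))) stopf("no feasible hyperparameter grid entry")
  ord <- order(-scores, grid$num_trees, -grid$min_node)
  best <- grid[ord[1], , drop = FALSE]
  structure(best, scores = scores)
}

#' Train a random-forest confidence model
#'
#' @param X predictor matrix
#' @param y class labels
#' @param num_trees,min_node,mtry forest hyperparameters (NULL mtry uses
#'   the default sqrt rule)
#' @param seed RNG seed
#' @return a ranger classification forest (per-tree votes retained via
#'   in-bag bookkeeping)
#' @export
trainConfidenceModel <- function(X, y, num_trees = 300L, min_node = 1L,
                                 mtry = NULL, seed = NULL) {
  if (is.null(seed)) seed <- 1L
  args <- list(x = as.data.frame(X), y = factor(y),
               num.trees = num_trees, min.node.size = min_node,
               keep.inbag = TRUE, importance = "impurity",
               num.threads = 1L, seed = as.integer(seed))
  if (!is.null(mtry)) args$mtry <- mtry
  do.call(ranger::ranger, args)
}

# per-tree class predictions as a records x trees integer matrix indexing
# model$forest$levels
treeVotes <- function(model, X, chunk = 20000L) {
  X <- as.data.frame(X)
  n <- nrow(X)
  out <- matrix(0L, n, model$num.trees)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    out[lo:hi, ] <- predict(model, X[lo:hi, , drop = FALSE],
                            predict.all = TRUE,
                            num.threads = 1L)$predictions
  }
  out
}

#' Predicted classes from a trained forest
#' @param model a forest from [trainConfidenceModel()]
#' @param X predictor matrix
#' @return factor of predicted classes
#' @export
predictClasses <- function(model, X) {
  predict(model, as.data.frame(X), num.threads = 1L)$predictions
}

#' Normalize per-class vote counts to model confidences
#'
#' Model confidence is the proportion of trees in the forest voting for a
#' class; e.g. 100 trees voting 35/10/5/50 give 0.35/0.10/0.05/0.50.
#'
#' @param votes named numeric vector or matrix of per-class vote counts
#' @return confidences summing to 1 (per row for matrices)
#' @export
voteConfidence <- function(votes) {
  if (is.matrix(votes)) return(votes / rowSums(votes))
  votes / sum(votes)
}

#' Predict per-class model confidences
#'
#' @param model a trained randomForest
#' @param X predictor matrix
#' @return matrix (rows x classes) of vote proportions summing to 1
#' @export
predictConfidence <- function(model, X) {
  classes <- model$forest$levels
  pr <- treeVotes(model, X)
  votes <- vapply(seq_along(classes), function(k) rowSums(pr == k),
                  numeric(nrow(pr)))
  votes <- matrix(votes, nrow(pr), length(classes),
                  dimnames = list(NULL, classes))
  voteConfidence(votes)
}

#' Out-of-bag vote confidences on the training data
#'
#' Vote proportions counting only the trees for which each training record
#' was out of bag; used to pick change thresholds without a separate
#' held-out set.
#'
#' @param model a forest from [trainConfidenceModel()] (trained with
#'   in-bag bookkeeping)
#' @param X the training predictor matrix, in training row order
#' @return matrix (rows x classes) of OOB vote proportions
#' @export
oobVoteConfidence <- function(model, X) {
  classes <- model$forest$levels
  pr <- treeVotes(model, X)
  inbag <- matrix(unlist(model$inbag.counts), nrow(pr),
                  model$num.trees)
  oob <- inbag == 0L
  votes <- vapply(seq_along(classes), function(k)
    rowSums((pr == k) & oob), numeric(nrow(pr)))
  votes <- matrix(votes, nrow(pr), length(classes),
                  dimnames = list(NULL, classes))
  voteConfidence(votes)
}

#' Confidence cube for a whole feature cube
#'
#' @param model a trained forest from [trainConfidenceModel()]
#' @param cube a [FeatureCube-class]
#' @param features feature names the model was trained on
#' @param product product label for the result
#' @return a [ConfidenceCube-class]; incomplete pixel-years are NA
#' @export
predictConfidenceCube <- function(model, cube, features, product) {
  vals <- featureValues(cube)
  np <- dim(vals)[1]; ny <- dim(vals)[2]
  flat <- matrix(vals[, , features], np * ny, length(features),
                 dimnames = list(NULL, features))
  ok <- stats::complete.cases(flat) & as.vector(cube@complete)
  classes <- model$forest$levels
  conf <- matrix(NA_real_, np * ny, length(classes),
                 dimnames = list(NULL, classes))
  if (any(ok)) conf[ok, ] <- predictConfidence(model, flat[ok, , drop = FALSE])
  new("ConfidenceCube",
      values = array(conf, c(np, ny, length(classes)),
                     dimnames = list(NULL, cube@years, classes)),
      classes = classes, product = product, years = cube@years)
}

#' F1-optimal per-class confidence thresholds
#'
#' Scans thresholds 0.00-1.00 in steps of 0.01 and returns, per class, the
#' threshold maximizing F1 = 2PR/(P+R) of the rule "predict the class where
#' confidence >= threshold". Ties go to the lowest threshold; classes
#' absent from the truth get NA and a warning.
#'
#' @param confidences matrix (records x classes)
#' @param truth true class labels per record
#' @param classes classes to threshold (default: all confidence columns)
#' @return named numeric thresholds
#' @export
selectChangeThresholds <- function(confidences, truth,
                                   classes = colnames(confidences)) {
  grid <- seq(0, 1, by = 0.01)
  out <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    pos <- truth == cl
    if (!any(pos)) {
      warning(sprintf("class '%s' absent from truth; threshold undefined", cl))
      next
    }
    conf <- confidences[, cl]
    f1 <- vapply(grid, function(th) {
      pred <- conf >= th
      tp <- sum(pred & pos)
      if (tp == 0) return(0)
      prec <- tp / sum(pred)
      rec <- tp / sum(pos)
      2 * prec * rec / (prec + rec)
    }, numeric(1))
    out[cl] <- grid[which.max(f1)] # first maximum: lowest threshold
  }
  out
}
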