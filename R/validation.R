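# Grouped, stratified, weighted k-fold accuracy assessment with
# design-based standard errors.

#' Grouped, stratified fold assignment
#'
#' Every annual record of a plot shares one fold; plots are dealt
#' round-robin within stratum (after a seeded shuffle) so strata spread
#' across folds as evenly as group integrity allows.
#'
#' @param plots data.frame with `plot_id` and `stratum` (one row per plot,
#'   or per record - duplicates are collapsed)
#' @param k number of folds
#' @param seed RNG seed
#' @return named integer vector: fold per plot_id
#' @export
groupedStratifiedKfold <- function(plots, k = 10L, seed = 1L) {
  plots <- unique(plots[, c("plot_id", "stratum")])
  if (anyDuplicated(plots$plot_id))
    stopf("a plot_id appears in more than one stratum")
  if (k > nrow(plots)) stopf("k exceeds the number of plots")
  withSeed(seed, {
    fold <- integer(nrow(plots))
    cursor <- 0L
    for (s in unique(plots$stratum)) {
      idx <- which(plots$stratum == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
      cursor <- cursor + length(idx)
    }
    stats::setNames(fold, plots$plot_id)
  })
}

# stratified variance of a weighted mean of indicator x: sum_h P_h^2 s_h^2/n_h
stratVar <- function(x, stratum, P) {
  v <- 0
  for (h in names(P)) {
    xs <- x[stratum == h]
    n_h <- length(xs)
    if (n_h < 2) next
    v <- v + P[[h]]^2 * var(xs) / n_h
  }
  v
}

#' Weighted accuracy metrics with design-based standard errors
#'
#' Builds the weighted confusion matrix (truth rows, prediction columns),
#' then overall accuracy, per-class producer's (recall) and user's
#' (precision) accuracies, balanced accuracy (mean of defined producer's
#' accuracies) and kappa from the weighted marginals. With stratum labels
#' and population proportions supplied, standard errors use the stratified
#' random sampling estimator Var = sum_h P_h^2 s_h^2 / n_h on the
#' correctness indicator (ratio-variance analogue for the per-class
#' accuracies); without strata a single implicit stratum is used.
#' Accuracies and SEs are on the percent scale.
#'
#' @param truth,predicted class labels per record
#' @param weights per-record (inverse-probability) weights; default 1
#' @param stratum optional per-record stratum labels
#' @param proportions optional named population proportions per stratum
#' @return a [ValidationReport-class]
#' @export
weightedAccuracyMetrics <- function(truth, predicted, weights = NULL,
                                    stratum = NULL, proportions = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  n <- length(truth)
  stopifnot(length(predicted) == n)
  weights <- weights %||% rep(1, n)
  classes <- sort(unique(c(truth, predicted)))
  C <- matrix(0, length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  idx <- cbind(match(truth, classes), match(predicted, classes))
  for (r in seq_len(n)) C[idx[r, 1], idx[r, 2]] <- C[idx[r, 1], idx[r, 2]] +
      weights[r]
  tot <- sum(C)
  oa <- sum(diag(C)) / tot
  rowS <- rowSums(C); colS <- colSums(C)
  pa <- ifelse(rowS > 0, diag(C) / rowS, NA_real_)
  ua <- ifelse(colS > 0, diag(C) / colS, NA_real_)
  ba <- mean(pa, na.rm = TRUE)
  pe <- sum(rowS * colS) / tot^2
  kappa <- if (pe < 1) (oa - pe) / (1 - pe) else NA_real_

  if (is.null(stratum)) {
    stratum <- rep("all", n)
    proportions <- c(all = 1)
  }
  stratum <- as.character(stratum)
  if (is.null(proportions)) {
    tab <- tapply(weights, stratum, sum)
    proportions <- as.numeric(tab / sum(tab))
    names(proportions) <- names(tab)
  }
  correct <- as.numeric(truth == predicted)
  se_oa <- sqrt(stratVar(correct, stratum, proportions))
  # ratio-variance SEs for per-class accuracies
  ratioSE <- function(num_ind, den_ind, R) {
    if (is.na(R)) return(NA_real_)
    D <- 0
    for (h in names(proportions))
      D <- D + proportions[[h]] * mean(den_ind[stratum == h])
    if (D <= 0) return(NA_real_)
    e <- num_ind - R * den_ind
    sqrt(stratVar(e, stratum, proportions)) / D
  }
  pa_se <- ua_se <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    pa_se[ci] <- ratioSE(as.numeric(truth == cl & predicted == cl),
                         as.numeric(truth == cl), pa[ci])
    ua_se[ci] <- ratioSE(as.numeric(truth == cl & predicted == cl),
                         as.numeric(predicted == cl), ua[ci])
  }
  ndef <- sum(!is.na(pa))
  se_ba <- sqrt(sum(pa_se[!is.na(pa)]^2, na.rm = TRUE)) / max(ndef, 1)

  overall <- data.frame(overall_accuracy = 100 * oa,
                        overall_accuracy_se = 100 * se_oa,
                        balanced_accuracy = 100 * ba,
                        balanced_accuracy_se = 100 * se_ba,
                        kappa = kappa)
  by_class <- data.frame(class = classes,
                         users_accuracy = 100 * ua,
                         users_se = 100 * ua_se,
                         producers_accuracy = 100 * pa,
                         producers_se = 100 * pa_se,
                         stringsAsFactors = FALSE, row.names = NULL)
  new("ValidationReport", confusion = C, overall = overall,
      by_class = by_class, n = as.integer(n))
}

#' 95% confidence-interval half-width from a standard error
#'
#' @param se standard error
#' @param level confidence level (default 0.95)
#' @return half-width (1.96 x SE at the default level)
#' @export
ciHalfWidth <- function(se, level = 0.95) {
  stats::qnorm(1 - (1 - level) / 2) * se
}
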