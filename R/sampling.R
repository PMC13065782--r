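# Disproportionate stratified random sampling: loss-stratum derivation,
# midway equal/proportional allocation with caps and fixed counts, stratum
# weights, and the seeded location draw.

#' Derive the vegetation-loss stratum from NBR segmentations
#'
#' A pixel belongs to the loss stratum when any fitted segment of its NBR
#' segmentation decreased by more than the threshold (strictly below
#' -0.2 by default; a magnitude of exactly -0.2 stays stable).
#'
#' @param fits a single [LTSegmentation-class] or a list of them (one per
#'   pixel), fit on NBR
#' @param threshold loss threshold on segment magnitude (default -0.2)
#' @return logical: TRUE = loss stratum
#' @export
deriveLossStratum <- function(fits, threshold = -0.2) {
  one <- function(f) {
    if (is.null(f)) return(NA)
    any(segments(f)$magnitude < threshold)
  }
  if (is(fits, "LTSegmentation")) return(one(fits))
  vapply(fits, one, logical(1))
}

#' Allocate a stratified sample
#'
#' Fixed strata receive their fixed counts. The remainder starts from an
#' allocation midway between equal and proportional shares of the free
#' strata, caps are applied, and the surplus is re-allocated proportionally
#' among uncapped strata until stable; largest-remainder rounding forces
#' the counts to sum exactly to N.
#'
#' @param strata data.frame with columns `name`, `proportion` (population
#'   share, summing to 1), and optional `fixed` and `cap` (NA = none)
#' @param N total sample size
#' @return named integer counts per stratum
#' @export
allocateSample <- function(strata, N) {
  stopifnot(is.data.frame(strata), all(c("name", "proportion") %in%
                                         names(strata)))
  if (abs(sum(strata$proportion) - 1) > 1e-6)
    stopf("stratum proportions must sum to 1")
  fixed <- strata$fixed %||% rep(NA_real_, nrow(strata))
  cap <- strata$cap %||% rep(NA_real_, nrow(strata))
  counts <- stats::setNames(rep(0L, nrow(strata)), strata$name)
  isFixed <- !is.na(fixed)
  counts[isFixed] <- as.integer(fixed[isFixed])
  Nrem <- N - sum(counts)
  if (Nrem < 0) stopf("fixed counts exceed N")
  free <- which(!isFixed)
  if (!length(free)) {
    if (Nrem > 0) stopf("no free stratum to absorb remaining samples")
    return(counts)
  }
  P <- strata$proportion[free]
  P <- P / sum(P)
  k <- length(free)
  alloc <- (Nrem / k + Nrem * P) / 2 # midway between equal and proportional
  capf <- cap[free]
  # recursive proportional re-allocation of the over-cap surplus
  repeat {
    over <- !is.na(capf) & alloc > capf
    atcap <- !is.na(capf) & alloc >= capf
    if (!any(over)) break
    surplus <- sum(alloc[over] - capf[over])
    alloc[over] <- capf[over]
    open <- !atcap
    if (!any(open)) {
      if (surplus > 1e-9) stopf("caps infeasible for requested N")
      break
    }
    alloc[open] <- alloc[open] + surplus * P[open] / sum(P[open])
  }
  # largest-remainder rounding to hit Nrem exactly, respecting caps
  fl <- floor(alloc)
  shortfall <- round(Nrem - sum(fl))
  rem <- alloc - fl
  roundable <- is.na(capf) | fl + 1 <= capf
  ord <- order(-rem, seq_along(rem))
  add <- integer(length(alloc))
  for (i in ord) {
    if (shortfall <= 0) break
    if (roundable[i]) { add[i] <- 1L; shortfall <- shortfall - 1L }
  }
  if (shortfall > 0) stopf("caps infeasible for requested N")
  counts[free] <- as.integer(fl + add)
  counts
}

#' Stratum weights of a realized design
#'
#' The stratum weight is the sample share divided by the population share,
#' W_h = (n_h/N) / P_h; its reciprocal is the inverse-probability weight
#' attached to each record of the stratum during validation.
#'
#' @param counts named per-stratum sample counts
#' @param proportions per-stratum population proportions (same order)
#' @param N total sample size (default: sum of counts)
#' @return a [SampleDesign-class]
#' @export
computeWeights <- function(counts, proportions, N = sum(counts)) {
  if (any(counts == 0 & proportions > 0))
    stopf("zero count in a stratum with nonzero population share")
  W <- (counts / N) / proportions
  design <- data.frame(name = names(counts) %||% seq_along(counts),
                       proportion = proportions, count = as.integer(counts),
                       weight = W, inv_weight = 1 / W,
                       stringsAsFactors = FALSE)
  new("SampleDesign", design = design, total = as.integer(N))
}

#' Draw plot locations within strata
#'
#' Uniform random sampling without replacement within each stratum.
#'
#' @param strata integer stratum raster (matrix) or vector
#' @param counts named counts per stratum value (names = stratum codes as
#'   character)
#' @param seed RNG seed
#' @return data.frame (plot_id, pixel, row, col, stratum)
#' @export
drawSample <- function(strata, counts, seed = 1L) {
  nr <- if (is.matrix(strata)) nrow(strata) else NA_integer_
  sv <- as.vector(strata)
  withSeed(seed, {
    picks <- lapply(names(counts), function(s) {
      pool <- which(sv == as.integer(s))
      n <- counts[[s]]
      if (length(pool) < n)
        stopf("stratum %s has %d pixels, %d requested", s, length(pool), n)
      sort(sample(pool, n))
    })
    pixel <- unlist(picks)
    data.frame(plot_id = seq_along(pixel), pixel = pixel,
               row = if (is.na(nr)) NA_integer_ else ((pixel - 1L) %% nr) + 1L,
               col = if (is.na(nr)) NA_integer_ else ((pixel - 1L) %/% nr) + 1L,
               stratum = rep(as.integer(names(counts)),
                             vapply(picks, length, integer(1))))
  })
}

#' Published per-stratum sample counts, proportions and weights
#'
#' The printed design table of the national calibration sample (four study
#' areas), shipped as a CSV fixture. Used to exercise the weight
#' arithmetic: recomputing W = (n/N)/P from the printed counts and
#' proportions reproduces the printed weights for well-conditioned rows.
#'
#' @param study_area optional filter ("CONUS", "SEAK", "PRUSVI", "HI")
#' @return data.frame (study_area, stratum, count, proportion_pct, weight)
#' @export
stratumTable <- function(study_area = NULL) {
  path <- system.file("extdata", "stratum_table.csv",
                      package = "ChangeScape")
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(study_area)) tab <- tab[tab$study_area %in% study_area, ]
  tab
}
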