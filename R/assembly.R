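# Map assembly: thresholded argmax over class confidences subject to
# ancillary rules, plus the thematic cross-walks between levels.

#' Assemble annual class maps from a confidence cube
#'
#' Per pixel-year the candidate set is every class passing its threshold
#' (if any) and not forbidden by a rule; the candidate with the highest
#' confidence wins, ties broken by the priority order. For the Change
#' product (`stable_class` given) only the change classes compete and the
#' output falls back to the stable class when none passes. Rules are pure
#' predicates over named ancillary masks: `list(class =, mask =, action =
#' "forbid"|"min_threshold", threshold =)`.
#'
#' @param conf a [ConfidenceCube-class]
#' @param thresholds named per-class minimum confidences (optional)
#' @param rules list of rule descriptors (see above)
#' @param masks named list of logical pixel rasters referenced by rules
#' @param stable_class fallback class when no candidate passes (Change
#'   product); NULL for products where every class competes
#' @param priority class priority order for ties (default registry order)
#' @return a [ClassMapSeries-class] at the finest thematic level
#' @export
assembleMap <- function(conf, thresholds = NULL, rules = list(),
                        masks = list(), stable_class = NULL,
                        priority = NULL) {
  classes <- classRegistry(conf)
  vals <- confidenceValues(conf)
  np <- dim(vals)[1]; ny <- dim(vals)[2]
  codes <- matrix(NA_integer_, np, ny)
  for (yi in seq_len(ny)) {
    cy <- matrix(vals[, yi, ], np, length(classes),
                 dimnames = list(NULL, classes))
    codes[, yi] <- assembleRecords(cy, seq_len(np), thresholds, rules,
                                   masks, stable_class, priority)
  }
  new("ClassMapSeries", codes = codes, classes = classes,
      product = conf@product, level = if (conf@product == "Land Cover") 4L
      else 3L, years = conf@years)
}

#' Record-level assembly core
#'
#' The same thresholded, rule-constrained argmax that [assembleMap()]
#' applies per year, exposed at the record level so the accuracy
#' assessment can mirror assembly exactly.
#'
#' @param conf records x classes confidence matrix (named columns)
#' @param pixels pixel id per record (indexes the rule masks)
#' @inheritParams assembleMap
#' @return integer class codes into `colnames(conf)` (NA for null records)
#' @export
assembleRecords <- function(conf, pixels, thresholds = NULL, rules = list(),
                            masks = list(), stable_class = NULL,
                            priority = NULL) {
  classes <- colnames(conf)
  priority <- priority %||% classes
  n <- nrow(conf)
  thr <- stats::setNames(rep(-Inf, length(classes)), classes)
  if (!is.null(thresholds)) {
    known <- intersect(names(thresholds), classes)
    thr[known] <- thresholds[known]
  }
  forbid <- matrix(FALSE, n, length(classes), dimnames = list(NULL, classes))
  minthr <- matrix(-Inf, n, length(classes), dimnames = list(NULL, classes))
  for (r in rules) {
    if (!r$mask %in% names(masks))
      stopf("rule references unknown ancillary mask '%s'", r$mask)
    m <- as.vector(masks[[r$mask]])[pixels]
    if (!r$class %in% classes) next
    if (r$action == "forbid") {
      forbid[m, r$class] <- TRUE
    } else if (r$action == "min_threshold") {
      minthr[m, r$class] <- pmax(minthr[m, r$class], r$threshold)
    } else stopf("unknown rule action '%s'", r$action)
  }
  competing <- if (is.null(stable_class)) classes else
    setdiff(classes, stable_class)
  elig <- !is.na(conf)
  for (cl in classes) {
    pass <- conf[, cl] >= pmax(thr[cl], minthr[, cl])
    elig[, cl] <- elig[, cl] & pass & !forbid[, cl]
  }
  elig[, setdiff(classes, competing)] <- FALSE
  score <- conf
  score[!elig] <- -Inf
  # argmax with priority tie-break via an infinitesimal rank penalty
  tie <- matrix(rep(match(classes, priority) * 1e-12, each = n), n)
  pick <- max.col(score - tie, ties.method = "first")
  none <- !apply(elig, 1, any)
  valid <- stats::complete.cases(conf)
  out <- ifelse(none, NA_integer_, pick)
  if (!is.null(stable_class))
    out[none & valid] <- match(stable_class, classes)
  as.integer(out)
}

xwalkLookup <- function(x, table, from, to) {
  i <- match(x, table[[from]])
  if (anyNA(i) && !all(is.na(x[is.na(i)])))
    stopf("unknown class: %s",
          paste(unique(x[is.na(i) & !is.na(x)]), collapse = ", "))
  table[[to]][i]
}

#' Cross-walk change processes (or Level-3 change classes) to a level
#'
#' Fire/Harvest/Mechanical/Wind/Ice/Hydrology/Debris/Other bin to Fast
#' Loss, the declines to Slow Loss, Growth/Recovery to Gain; Gain rolls up
#' to Stable at Level 1.
#'
#' @param x change process names or Level-3 class names
#' @param level target level (1, 2 or 3)
#' @return class names at the requested level
#' @export
crosswalkChange <- function(x, level = 3L) {
  lvl <- paste0("level", level)
  stopifnot(lvl %in% c("level1", "level2", "level3"))
  isProc <- x %in% CHANGE_XWALK$process
  out <- x
  out[isProc] <- xwalkLookup(x[isProc], CHANGE_XWALK, "process", lvl)
  if (any(!isProc)) {
    l3 <- unique(CHANGE_XWALK[, c("level3", "level2", "level1")])
    out[!isProc] <- xwalkLookup(x[!isProc], l3, "level3", lvl)
  }
  out
}

#' Cross-walk primary/secondary land cover to a level
#'
#' A secondary cover is used only when it sits higher on the successional
#' sequence (Barren < Grass/Forb/Herb < Shrub/Tall Shrub < Tree) than the
#' primary; among several eligible secondaries the highest is used. Water
#' and Snow or Ice never mix. With `level < 4` the Level-4 class is rolled
#' down the table columns. Level-4 class names are also accepted directly
#' for rolling down.
#'
#' @param primary primary cover classes (or Level-4 class names)
#' @param secondary secondary covers: character vector, or list of
#'   character vectors, ";"-separated strings, "" or NA for none
#' @param level target level (1-4)
#' @return class names at the requested level
#' @export
crosswalkLandCover <- function(primary, secondary = NA_character_,
                               level = 4L) {
  lvl <- paste0("level", level)
  n <- length(primary)
  if (!is.list(secondary)) {
    secondary <- rep_len(as.character(secondary), n)
    secondary <- strsplit(ifelse(is.na(secondary), "", secondary), ";",
                          fixed = TRUE)
  }
  l4 <- character(n)
  direct <- primary %in% LANDCOVER_XWALK$level4 &
    !primary %in% LANDCOVER_XWALK$primary
  l4[direct] <- primary[direct]
  for (i in which(!direct)) {
    p <- primary[i]
    sec <- secondary[[i]]
    sec <- sec[nzchar(sec) & !is.na(sec)]
    use <- NA_character_
    if (length(sec) && !p %in% c("Water", "Snow or Ice")) {
      pr <- SUCCESSION[p]
      ranks <- SUCCESSION[sec]
      elig <- !is.na(ranks) & ranks > pr
      ranks[!elig] <- 0
      if (any(elig)) use <- sec[which.max(ranks)]
    }
    row <- which(LANDCOVER_XWALK$primary == p &
                   (is.na(LANDCOVER_XWALK$secondary) & is.na(use) |
                      !is.na(LANDCOVER_XWALK$secondary) &
                      LANDCOVER_XWALK$secondary %in% use))
    if (!length(row)) { # no pairing row: fall back to the identity row
      row <- which(LANDCOVER_XWALK$primary == p &
                     is.na(LANDCOVER_XWALK$secondary))
    }
    if (!length(row)) stopf("unknown land cover class '%s'", p)
    l4[i] <- LANDCOVER_XWALK$level4[row[1]]
  }
  if (level == 4L) return(l4)
  xwalkLookup(l4, LANDCOVER_XWALK, "level4", lvl)
}

#' Cross-walk land-use classes to a level
#'
#' @param x Level-3 land-use class names
#' @param level target level (1, 2 or 3)
#' @return class names at the requested level
#' @export
crosswalkLandUse <- function(x, level = 3L) {
  lvl <- paste0("level", level)
  stopifnot(lvl %in% c("level1", "level2", "level3"))
  xwalkLookup(x, LANDUSE_XWALK, "level3", lvl)
}

#' Cross-walk an assembled map series to a coarser level
#'
#' @param maps a [ClassMapSeries-class]
#' @param level target thematic level
#' @return a [ClassMapSeries-class] at the requested level
#' @export
crosswalkMapSeries <- function(maps, level) {
  cls <- classRegistry(maps)
  newcls <- switch(maps@product,
                   "Change" = crosswalkChange(cls, level),
                   "Land Cover" = crosswalkLandCover(cls, level = level),
                   "Land Use" = crosswalkLandUse(cls, level),
                   stopf("unknown product '%s'", maps@product))
  registry <- unique(newcls)
  codes <- matrix(match(newcls, registry)[classCodes(maps)],
                  nrow(classCodes(maps)))
  new("ClassMapSeries", codes = codes, classes = registry,
      product = maps@product, level = as.integer(level),
      years = maps@years)
}
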