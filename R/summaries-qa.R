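# Change-year summary layers and the 15-bit QA provenance word.

#' Most recent year a class occurred
#'
#' @param classes annual class labels
#' @param years matching calendar years
#' @param target class of interest
#' @return the latest year the class occurs, or NA when absent
#' @export
mostRecentYear <- function(classes, years, target) {
  hit <- which(classes == target)
  if (!length(hit)) return(NA_integer_)
  as.integer(max(years[hit]))
}

#' Year of peak model confidence for a class
#'
#' Among years assembled as the target class, returns the year with the
#' highest model confidence (ties to the earliest year).
#'
#' @param confidences annual confidence of the target class
#' @param classes annual assembled class labels
#' @param years matching calendar years
#' @param target class of interest
#' @return the peak-confidence year, or NA when the class was never
#'   assembled
#' @export
mostProbableYear <- function(confidences, classes, years, target) {
  hit <- which(classes == target)
  if (!length(hit)) return(NA_integer_)
  as.integer(years[hit[which.max(confidences[hit])]])
}

#' Pack QA provenance into a 15-bit word
#'
#' Bit 0 carries the not-interpolated flag (0 = interpolated, 1 = not
#' interpolated), bits 1-5 the sensor code (4, 5, 7, 8, 9 Landsat; 21
#' Sentinel-2a; 22 Sentinel-2b), bits 6-14 the Julian day (1-365),
#' LSB-first. `unpackQA()` inverts exactly.
#'
#' @param interpolated logical: was the pixel-year value interpolated
#' @param sensor sensor code
#' @param day Julian day in 1-365
#' @return integer QA word(s)
#' @export
packQA <- function(interpolated, sensor, day) {
  sensor <- as.integer(sensor); day <- as.integer(day)
  if (any(!sensor %in% SENSOR_CODES))
    stopf("sensor code outside registry {%s}",
          paste(SENSOR_CODES, collapse = ","))
  if (any(day < 1L | day > 365L)) stopf("Julian day outside 1-365")
  as.integer(!interpolated) + bitwShiftL(sensor, 1L) + bitwShiftL(day, 6L)
}

#' @rdname packQA
#' @param word integer QA word(s) from [packQA()]
#' @return `unpackQA`: data.frame with interpolated, sensor, day
#' @export
unpackQA <- function(word) {
  word <- as.integer(word)
  data.frame(interpolated = bitwAnd(word, 1L) == 0L,
             sensor = bitwAnd(bitwShiftR(word, 1L), 31L),
             day = bitwShiftR(word, 6L))
}

#' QA provenance words for a composite series
#'
#' @param composites a gap-filled [CompositeSeries-class]
#' @return integer matrix pixel x year of QA words (NA where no provenance
#'   exists, i.e. rejected pixels)
#' @export
qaStack <- function(composites) {
  np <- dim(compositeBands(composites))[1]
  ny <- length(composites@years)
  out <- matrix(NA_integer_, np, ny)
  interp <- interpolatedFlags(composites)
  sens <- composites@sensor
  doy <- composites@doy
  # interpolated years inherit the nearest valid year's sensor/day
  for (p in seq_len(np)) {
    valid <- which(!is.na(sens[p, ]))
    if (!length(valid)) next
    near <- vapply(seq_len(ny), function(yi)
      valid[which.min(abs(valid - yi))], integer(1))
    out[p, ] <- packQA(interp[p, ], sens[p, near], doy[p, near])
  }
  out
}

#' Change-year summary layers
#'
#' For each requested change class returns the most-recent and
#' most-probable year per pixel, with the confidence at the most-probable
#' year.
#'
#' @param maps an assembled [ClassMapSeries-class]
#' @param conf the matching [ConfidenceCube-class]
#' @param target_classes classes to summarize (default: all non-Stable)
#' @return named list of per-class data.frames (pixel, most_recent,
#'   most_probable, confidence)
#' @export
changeYearSummaries <- function(maps, conf,
                                target_classes = setdiff(classRegistry(maps),
                                                         "Stable")) {
  codes <- classCodes(maps)
  classes <- classRegistry(maps)
  years <- mapYears(maps)
  vals <- confidenceValues(conf)
  out <- list()
  for (cl in target_classes) {
    ci <- match(cl, classRegistry(conf))
    mr <- mp <- rep(NA_integer_, nrow(codes))
    cf <- rep(NA_real_, nrow(codes))
    for (p in seq_len(nrow(codes))) {
      lab <- classes[codes[p, ]]
      mr[p] <- mostRecentYear(lab, years, cl)
      mp[p] <- mostProbableYear(vals[p, , ci], lab, years, cl)
      if (!is.na(mp[p])) cf[p] <- vals[p, match(mp[p], years), ci]
    }
    out[[cl]] <- data.frame(pixel = seq_len(nrow(codes)), most_recent = mr,
                            most_probable = mp, confidence = cf)
  }
  out
}
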