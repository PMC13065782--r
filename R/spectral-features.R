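# Spectral indices and the tasseled-cap transform.

normDiff <- function(a, b) {
  den <- a + b
  out <- (a - b) / den
  out[den == 0] <- NA_real_
  out
}

#' Tasseled-cap transform
#'
#' @param bands matrix (rows = observations) or named vector of the six
#'   reflectance bands
#' @param coefs 3 x 6 coefficient matrix (rows TCB/TCG/TCW); defaults to the
#'   Crist (1985) reflectance-factor set
#' @return matrix with TCB, TCG, TCW columns
#' @export
tasseledCap <- function(bands, coefs = TC_COEFS) {
  if (is.null(dim(bands))) bands <- matrix(bands, 1,
                                           dimnames = list(NULL, names(bands)))
  as.matrix(bands[, BAND_NAMES, drop = FALSE]) %*% t(coefs)
}

#' Spectral features of a composite
#'
#' Computes NDVI, NBR, NDMI, NDSI, tasseled-cap brightness/greenness/wetness
#' and the brightness-greenness angle (degrees) from six-band reflectance.
#' Normalized-difference features are NA where the denominator is zero.
#'
#' @inheritParams tasseledCap
#' @return matrix (observations x 8 features)
#' @export
spectralFeatures <- function(bands, coefs = TC_COEFS) {
  if (is.null(dim(bands))) bands <- matrix(bands, 1,
                                           dimnames = list(NULL, names(bands)))
  b <- as.matrix(bands[, BAND_NAMES, drop = FALSE])
  tc <- tasseledCap(b, coefs)
  angle <- atan2(tc[, "TCG"], tc[, "TCB"]) * 180 / pi
  out <- cbind(NDVI = normDiff(b[, "nir"], b[, "red"]),
               NBR = normDiff(b[, "nir"], b[, "swir2"]),
               NDMI = normDiff(b[, "nir"], b[, "swir1"]),
               NDSI = normDiff(b[, "green"], b[, "swir1"]),
               tc, TCA = angle)
  out
}

#' Index stack of a composite series
#'
#' Expands a gap-filled [CompositeSeries-class] into the 14-layer annual
#' stack (six bands, four normalized-difference indices, three tasseled-cap
#' components and the brightness/greenness angle) fed to temporal
#' segmentation.
#'
#' @param composites a [CompositeSeries-class]
#' @return numeric array pixel x year x 14, dimnames carrying index names
#' @export
indexStack <- function(composites) {
  bands <- compositeBands(composites)
  np <- dim(bands)[1]; ny <- dim(bands)[2]
  out <- array(NA_real_, c(np, ny, length(INDEX_NAMES)),
               dimnames = list(NULL, composites@years, INDEX_NAMES))
  out[, , seq_len(6)] <- bands
  flat <- matrix(bands, np * ny, 6, dimnames = list(NULL, BAND_NAMES))
  feats <- spectralFeatures(flat)
  for (k in seq_len(8))
    out[, , 6 + k] <- matrix(feats[, k], np, ny)
  out
}
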