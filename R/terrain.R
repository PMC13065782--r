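# Terrain predictors: Horn slope/aspect and topographic position index
# (TPI) at circular windows, plus assembly of the full per-pixel-per-year
# predictor cube.

padEdges <- function(m) {
  m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

#' Terrain predictor rasters from a DEM
#'
#' Slope and aspect use Horn's eight-neighbour finite differences (edges
#' replicated); aspect is measured clockwise from north and encoded as its
#' sine and cosine (both 0 on flat cells). TPI is elevation minus the mean
#' elevation within a circular window of the stated pixel diameter; windows
#' shrink at raster edges.
#'
#' @param dem elevation matrix (row 1 = north), metres
#' @param cellsize pixel size in metres (default 30)
#' @param windows TPI window diameters in pixels
#' @return matrix (pixels x 7): elevation, slope (degrees), sin/cos aspect,
#'   one TPI column per window
#' @export
terrainFeatures <- function(dem, cellsize = 30, windows = c(11L, 21L, 41L)) {
  nr <- nrow(dem); nc <- ncol(dem)
  p <- padEdges(dem)
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  a <- p[i - 1, j - 1]; b <- p[i - 1, j]; cc <- p[i - 1, j + 1]
  d <- p[i, j - 1];                        f <- p[i, j + 1]
  g <- p[i + 1, j - 1]; h <- p[i + 1, j]; ii <- p[i + 1, j + 1]
  zx <- ((cc + 2 * f + ii) - (a + 2 * d + g)) / (8 * cellsize)
  zy <- ((a + 2 * b + cc) - (g + 2 * h + ii)) / (8 * cellsize) # north +
  slope <- atan(sqrt(zx^2 + zy^2)) * 180 / pi
  az <- atan2(-zx, -zy) # azimuth of steepest descent, clockwise from north
  sin_a <- sin(az); cos_a <- cos(az)
  flat <- slope == 0
  sin_a[flat] <- 0; cos_a[flat] <- 0

  tpis <- lapply(windows, function(w) dem - circularMean(dem, w))
  out <- cbind(elevation = as.vector(dem), slope = as.vector(slope),
               sin_aspect = as.vector(sin_a), cos_aspect = as.vector(cos_a))
  for (k in seq_along(windows))
    out <- cbind(out, as.vector(tpis[[k]]))
  colnames(out) <- c("elevation", "slope", "sin_aspect", "cos_aspect",
                     paste0("TPI_", windows))
  out
}

# mean over a circular window of given pixel diameter, window shrinking at
# the edges (mean over valid cells only)
circularMean <- function(m, diameter) {
  r <- (diameter - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (dx in -floor(r):floor(r)) {
    for (dy in -floor(r):floor(r)) {
      if (dx * dx + dy * dy > r * r) next
      sr_lo <- max(1, 1 - dy); sr_hi <- min(nr, nr - dy)
      sc_lo <- max(1, 1 - dx); sc_hi <- min(nc, nc - dx)
      if (sr_lo > sr_hi || sc_lo > sc_hi) next
      sr <- sr_lo:sr_hi
      sc <- sc_lo:sc_hi
      acc[sr, sc] <- acc[sr, sc] + m[sr + dy, sc + dx]
      cnt[sr, sc] <- cnt[sr, sc] + 1
    }
  }
  acc / cnt
}

#' Assemble the full predictor cube
#'
#' Joins the segmentation block (14 indices x 5 metrics), the harmonic
#' block (7 bands x 8 metrics) and the 7 year-constant terrain predictors
#' into one pixel x year x feature cube with a feature registry. Pixel-years
#' missing any block are flagged incomplete, never silently imputed.
#'
#' @param lt pixel x year x feature array from [ltFeatureStack()]
#' @param ccdc pixel x year x feature array from [ccdcFeatureStack()]
#' @param terrain pixels x 7 matrix from [terrainFeatures()]
#' @param years calendar years (must match both annual blocks)
#' @return a [FeatureCube-class]
#' @export
buildFeatureMatrix <- function(lt, ccdc, terrain, years) {
  np <- dim(lt)[1]; ny <- dim(lt)[2]
  if (!identical(dim(ccdc)[1:2], dim(lt)[1:2]) || nrow(terrain) != np)
    stopf("predictor blocks disagree on grid or years")
  if (ny != length(years)) stopf("year range mismatch")
  ltn <- dimnames(lt)[[3]]; ccn <- dimnames(ccdc)[[3]]
  tn <- paste0("TERRAIN_", colnames(terrain))
  nf <- length(ltn) + length(ccn) + length(tn)
  values <- array(NA_real_, c(np, ny, nf),
                  dimnames = list(NULL, years, c(ltn, ccn, tn)))
  values[, , seq_along(ltn)] <- lt
  values[, , length(ltn) + seq_along(ccn)] <- ccdc
  for (k in seq_along(tn))
    values[, , length(ltn) + length(ccn) + k] <- terrain[, k]
  registry <- data.frame(
    name = c(ltn, ccn, tn),
    block = c(rep("landtrendr", length(ltn)), rep("ccdc", length(ccn)),
              rep("terrain", length(tn))),
    stringsAsFactors = FALSE)
  complete <- matrix(TRUE, np, ny)
  for (k in seq_len(nf))
    complete <- complete & !is.na(values[, , k])
  new("FeatureCube", values = values, registry = registry,
      years = as.integer(years), complete = complete)
}
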