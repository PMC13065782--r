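# Raster and table I/O. Raster stacks are stored as multi-directory TIFF
# (one 32-bit grayscale directory per band) with a JSON sidecar carrying
# band names, grid geometry, per-band scaling, nodata handling and
# optional class-name metadata. Values are scaled affinely into [0, 0.9];
# NA is encoded as 1.0. Integer stacks (flagged in the sidecar) are
# rounded on read, which makes e.g. uint16 QA words round-trip
# bit-exactly.

sidecarPath <- function(path) paste0(path, ".json")

#' Write a raster stack
#'
#' @param x matrix (pixels x bands) or 3-d array (rows x cols x bands)
#' @param path output TIFF path (a JSON sidecar is written next to it)
#' @param dim_grid c(n_rows, n_cols); required when `x` is a matrix
#' @param band_names band names stored in the sidecar
#' @param integer flag integer-valued data (rounded on read)
#' @param meta extra metadata list merged into the sidecar (e.g. class
#'   names, georeferencing)
#' @export
writeRasterStack <- function(x, path, dim_grid = NULL, band_names = NULL,
                             integer = FALSE, meta = list()) {
  if (is.matrix(x)) {
    stopifnot(!is.null(dim_grid))
    arr <- array(x, c(dim_grid[1], dim_grid[2], ncol(x)))
    band_names <- band_names %||% colnames(x)
  } else {
    arr <- x
    dim_grid <- dim(arr)[1:2]
    band_names <- band_names %||% dimnames(arr)[[3]]
  }
  nb <- dim(arr)[3]
  scale <- numeric(nb); offset <- numeric(nb)
  enc <- vector("list", nb)
  for (b in seq_len(nb)) {
    v <- arr[, , b, drop = TRUE]
    if (is.null(dim(v))) v <- matrix(v, dim(arr)[1], dim(arr)[2])
    fin <- is.finite(v)
    lo <- if (any(fin)) min(v[fin]) else 0
    hi <- if (any(fin)) max(v[fin]) else 1
    span <- if (hi > lo) hi - lo else 1
    offset[b] <- lo; scale[b] <- span / 0.9
    e <- (v - lo) / span * 0.9
    e[!fin] <- 1
    enc[[b]] <- e
  }
  tiff::writeTIFF(enc, path, bits.per.sample = 32L)
  sidecar <- c(list(format_version = 1L,
                    n_rows = dim_grid[1], n_cols = dim_grid[2],
                    bands = as.list(band_names %||% paste0("b", seq_len(nb))),
                    scale = scale, offset = offset, integer = integer,
                    crs = meta$crs %||% "local",
                    origin = meta$origin %||% c(0, 0),
                    cellsize = meta$cellsize %||% 30),
               meta[setdiff(names(meta), c("crs", "origin", "cellsize"))])
  jsonlite::write_json(sidecar, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster stack written by [writeRasterStack()]
#'
#' @param path TIFF path
#' @param as_matrix return pixels x bands matrix instead of an array
#' @return array (rows x cols x bands) or matrix, with band names and the
#'   sidecar attached as the `meta` attribute
#' @export
readRasterStack <- function(path, as_matrix = FALSE) {
  sc <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  dirs <- tiff::readTIFF(path, all = TRUE)
  nb <- length(dirs)
  out <- array(NA_real_, c(dim(dirs[[1]]), nb))
  for (b in seq_len(nb)) {
    v <- dirs[[b]]
    na <- v > 0.95
    dec <- v * sc$scale[b] + sc$offset[b]
    if (isTRUE(sc$integer)) dec <- round(dec)
    dec[na] <- NA
    out[, , b] <- dec
  }
  dimnames(out) <- list(NULL, NULL, unlist(sc$bands))
  if (as_matrix) {
    out <- matrix(out, prod(dim(out)[1:2]), nb,
                  dimnames = list(NULL, unlist(sc$bands)))
  }
  attr(out, "meta") <- sc
  out
}

#' Write assembled class maps with class-name metadata
#'
#' One band per year; the sidecar carries the class registry (code ->
#' name), product and level.
#'
#' @param maps a [ClassMapSeries-class]
#' @param path output TIFF path
#' @param dim_grid c(n_rows, n_cols)
#' @export
writeClassMaps <- function(maps, path, dim_grid) {
  codes <- classCodes(maps)
  writeRasterStack(codes, path, dim_grid,
                   band_names = as.character(mapYears(maps)),
                   integer = TRUE,
                   meta = list(classes = classRegistry(maps),
                               product = maps@product, level = maps@level))
  invisible(path)
}

#' Read class maps written by [writeClassMaps()]
#' @param path TIFF path
#' @return a [ClassMapSeries-class]
#' @export
readClassMaps <- function(path) {
  arr <- readRasterStack(path, as_matrix = TRUE)
  sc <- attr(arr, "meta")
  new("ClassMapSeries", codes = matrix(as.integer(arr), nrow(arr)),
      classes = unlist(sc$classes), product = sc$product,
      level = as.integer(sc$level),
      years = as.integer(unlist(sc$bands)))
}

#' Write truth records to CSV
#'
#' Schema: plot_id, year, change_process, primary_cover, secondary_covers
#' (";"-separated), land_use, stratum.
#'
#' @param truth truth data.frame (as from [sceneTruth()])
#' @param path CSV path
#' @export
writeTruthCSV <- function(truth, path) {
  out <- truth
  names(out)[names(out) == "stratum_id"] <- "stratum"
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthCSV
#' @return `readTruthCSV`: the truth data.frame
#' @export
readTruthCSV <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  names(out)[names(out) == "stratum"] <- "stratum_id"
  out$secondary_covers[is.na(out$secondary_covers)] <- ""
  out
}

#' Serialize a sample design to JSON
#' @param design a [SampleDesign-class]
#' @param path JSON path
#' @export
writeDesignJSON <- function(design, path) {
  jsonlite::write_json(list(total = design@total,
                            strata = designTable(design)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDesignJSON
#' @export
readDesignJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SampleDesign", design = x$strata, total = as.integer(x$total))
}
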