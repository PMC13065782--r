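#' @useDynLib ChangeScape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats approx coef cor median predict qchisq quantile rnorm
#'   runif sd var
#' @importFrom utils head read.csv write.csv
NULL

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package go
# through this so identical seeds give identical artifacts.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  force(code)
}

# derive a stream-specific child seed; kept below 2^31
childSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1103L + as.integer(offset) * 12347L) %% 2147483399L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# fractional year from calendar year + day of year (365-day convention)
fractionalYear <- function(year, doy) year + (doy - 0.5) / 365
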