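#' @useDynLib masterreg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor median p.adjust phyper pnorm pt quantile rnorm runif sd var
#' @importFrom utils read.delim write.table head combn
NULL

# Run code under a local RNG seed, restoring the caller's RNG state on exit.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stage seed derived from a global seed; stays < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
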