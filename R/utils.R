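#' @useDynLib scgdelin, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif median quantile sd
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this helper; no function
# touches the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

ms_to_samples <- function(ms, fs) ms / 1000 * fs

# Maximal runs of ones in a binary vector, inclusive 1-based [start, end].
runs_of_ones <- function(x) {
  x <- as.integer(x != 0)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start = starts[keep], end = ends[keep])
}

# Local extrema with strict neighbour comparison; plateaus resolve to the
# plateau midpoint (floor).  A plateau counts only if both flanks fall
# (peak) or both rise (valley); monotone shelves are not extrema.
find_extrema <- function(x, type = c("min", "max")) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  sgn <- sign(d)
  nz <- which(sgn != 0)
  if (length(nz) < 2L) return(integer(0))
  out <- integer(0)
  for (k in seq_len(length(nz) - 1L)) {
    i <- nz[k]; j <- nz[k + 1L]
    if (type == "min" && sgn[i] < 0 && sgn[j] > 0) {
      # valley spans samples (i+1) .. j (flat bottom allowed)
      out <- c(out, (i + 1L + j) %/% 2L)
    } else if (type == "max" && sgn[i] > 0 && sgn[j] < 0) {
      out <- c(out, (i + 1L + j) %/% 2L)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
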