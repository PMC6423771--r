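# Internal helpers: seeded evaluation, seed splitting, count resampling.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded operations do
#' not perturb the global random stream. A `NULL` seed evaluates the code
#' with the current stream (and leaves it advanced).
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive `n` sub-seeds (< 2^31) from one master seed, so
# that a single integer drives all stochastic stages of a pipeline.
split_seed <- function(seed, n) {
  if (is.null(seed)) {
    return(rep(list(NULL), n))
  }
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

# Multivariate hypergeometric draw: given integer cell counts `counts`
# totalling N, pick `n` of the N unit interactions uniformly without
# replacement and return the per-cell tallies. Uses position sampling over
# the cumulative count vector, which is exact and vectorized.
sample_counts_wor <- function(counts, n) {
  total <- sum(counts)
  n <- as.double(n)
  if (n < 0 || n > total) {
    stop(sprintf("cannot draw %g interactions from a source with %g", n, total),
         call. = FALSE)
  }
  out <- numeric(length(counts))
  if (n == 0) {
    return(out)
  }
  if (n == total) {
    return(as.numeric(counts))
  }
  nz <- which(counts > 0)
  cum <- cumsum(counts[nz])
  pos <- sample.int(total, n) # distinct interaction indices in 1..N
  idx <- findInterval(pos - 0.5, c(0, cum))
  tab <- tabulate(idx, nbins = length(nz))
  out[nz] <- tab
  out
}

# Largest-remainder apportionment of `total` into quotas proportional to
# `shares` (which need not sum to 1). Ties broken by position order.
largest_remainder <- function(total, shares) {
  shares <- shares / sum(shares)
  quota <- total * shares
  base <- floor(quota)
  left <- round(total - sum(base))
  if (left > 0) {
    frac <- quota - base
    give <- order(frac, decreasing = TRUE)[seq_len(left)]
    base[give] <- base[give] + 1
  }
  base
}

# Stop with a consistent message when a score is structurally undefined.
undefined_score <- function(reason) {
  warning(sprintf("undefined score: %s", reason), call. = FALSE)
  NA_real_
}
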