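# Uniform downsampling and pseudo-replicate construction.

#' Uniformly downsample a contact matrix
#'
#' Treats the matrix as the multiset of its individual interactions (one
#' per unit count over unordered bin pairs), draws exactly `n` of them
#' uniformly without replacement, and re-bins. This is a multivariate
#' hypergeometric draw, matching retention of a subset of the real
#' interactions rather than resampling with replacement.
#'
#' @param m raw `ContactMatrix`.
#' @param n number of interactions to keep, `0 <= n <= total_interactions(m)`.
#' @param seed integer seed.
#' @return a raw `ContactMatrix` with total exactly `n`.
#' @export
downsample <- function(m, n, seed = NULL) {
  validate_contact_matrix(m)
  if (!m$is_raw) stop("downsample needs a raw matrix", call. = FALSE)
  n_total <- total_interactions(m)
  if (n < 0 || n > n_total) {
    stop(sprintf("n must lie in [0, %g], got %g", n_total, n), call. = FALSE)
  }
  nb <- m$n_bins
  cells <- upper_cells(nb)
  kept <- with_seed(seed, sample_counts_wor(m$counts[cells], n))
  contact_matrix(symmetrize_upper(kept, nb), m$resolution, chrom = m$chrom,
                 is_raw = TRUE)
}

#' Pseudo-replicates from a pair of biological replicates
#'
#' Pools the two replicates by entrywise summation, then draws two
#' independent downsamples from the pooled matrix, each with
#' `round((N_a + N_b) / 2)` interactions (the average coverage of the two
#' seed replicates). Because their variation stems solely from statistical
#' sampling, pseudo-replicates bound from above the reproducibility
#' attainable by true biological replicates at that coverage.
#'
#' @param a,b raw `ContactMatrix` objects of identical shape.
#' @param seed integer seed.
#' @return list of two raw `ContactMatrix` pseudo-replicates.
#' @export
pseudo_replicates <- function(a, b, seed = NULL) {
  validate_contact_matrix(a)
  validate_contact_matrix(b)
  if (a$n_bins != b$n_bins) stop("a and b must have the same shape", call. = FALSE)
  pooled <- contact_matrix(a$counts + b$counts, a$resolution, chrom = a$chrom,
                           is_raw = TRUE)
  target <- round((total_interactions(a) + total_interactions(b)) / 2)
  seeds <- split_seed(seed, 2)
  list(downsample(pooled, target, seed = seeds[[1]]),
       downsample(pooled, target, seed = seeds[[2]]))
}

#' Coverage ladder: independent downsamples at several totals
#'
#' The default targets follow the study design (30, 25, 20, 15, 10, 5, 1
#' million interactions); callers with smaller matrices pass their own.
#'
#' @param m raw `ContactMatrix`.
#' @param targets interaction totals, all `<= total_interactions(m)`.
#' @param seed integer seed.
#' @return named list of `ContactMatrix`, one per target.
#' @export
coverage_ladder <- function(m, targets = c(30, 25, 20, 15, 10, 5, 1) * 1e6,
                            seed = NULL) {
  if (max(targets) > total_interactions(m)) {
    stop("largest target exceeds the available interactions", call. = FALSE)
  }
  seeds <- split_seed(seed, length(targets))
  out <- lapply(seq_along(targets), function(i) {
    downsample(m, targets[i], seed = seeds[[i]])
  })
  names(out) <- sprintf("cov_%g", targets)
  out
}
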