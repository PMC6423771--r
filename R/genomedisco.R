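# Random-walk concordance score: contact maps are treated as weighted
# networks, sqrt-normalized, converted to transition matrices and smoothed
# by t-step random walks; the normalized L1 distance between the smoothed
# maps, combined across t, gives a distance in [0, 2] and a score
# 1 - distance in [-1, 1].

#' Square-root coverage normalization
#'
#' Divides each entry by the square root of the product of its two bin
#' marginals: `out[i, j] = m[i, j] / sqrt(d_i * d_j)`. Bins with zero
#' marginal yield zero rows/columns. The output is symmetric and invariant
#' to global scaling of `m`.
#'
#' @param m a `ContactMatrix`.
#' @return a numeric matrix of the same shape.
#' @export
sqrt_normalize <- function(m) {
  validate_contact_matrix(m)
  d <- rowSums(m$counts)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  m$counts * outer(s, s)
}

#' Random-walk smoothing of a normalized contact map
#'
#' Row-normalizes `norm` to a transition matrix P (rows with zero degree
#' stay all-zero) and returns `P` raised to the power `t`: entry (j, i) is
#' the probability of reaching node i from node j in t steps of a random
#' walk biased by the edge weights. Small t reveals local domain
#' structure; larger t emphasizes compartments.
#'
#' @param norm non-negative square matrix (e.g. [sqrt_normalize()] output).
#' @param t walk length, integer >= 1.
#' @return the t-step transition matrix; every non-zero row sums to 1.
#' @export
random_walk_smooth <- function(norm, t) {
  if (t < 1 || t != round(t)) stop("t must be an integer >= 1", call. = FALSE)
  rs <- rowSums(norm)
  p <- norm / ifelse(rs > 0, rs, 1)
  out <- p
  for (step in seq_len(t - 1)) out <- out %*% p
  out
}

# number of bins with non-zero total counts
nnz_nodes <- function(m) sum(rowSums(m$counts) > 0)

#' Combined random-walk L1 distance between two contact maps
#'
#' For each walk length t, both maps are sqrt-normalized, row-normalized
#' and raised to the power t; the L1 distance (sum of absolute values of
#' the full difference matrix) is divided by the average number of nodes
#' with non-zero total counts in the two original maps. Distances across
#' several t are combined by the trapezoidal area under the curve in t
#' (a single t gives that distance directly). The result lies in \[0, 2\]:
#' for each node the maximal L1 difference is 2, attained when the node's
#' contacts are mutually exclusive between the maps.
#'
#' @param a,b `ContactMatrix` objects of identical shape.
#' @param t_values walk lengths; the study's optimum is `3`.
#' @return the combined distance, or `NA` (with a warning) when both maps
#'   are empty.
#' @export
disco_distance <- function(a, b, t_values = 3) {
  validate_contact_matrix(a)
  validate_contact_matrix(b)
  if (a$n_bins != b$n_bins) stop("a and b must have the same shape", call. = FALSE)
  keep <- rowSums(a$counts) > 0 | rowSums(b$counts) > 0
  if (!any(keep)) {
    return(undefined_score("both contact maps are empty"))
  }
  denom <- (nnz_nodes(a) + nnz_nodes(b)) / 2
  na <- sqrt_normalize(a)[keep, keep, drop = FALSE]
  nb <- sqrt_normalize(b)[keep, keep, drop = FALSE]
  t_values <- sort(unique(as.integer(t_values)))
  dists <- vapply(t_values, function(t) {
    pa <- random_walk_smooth(na, t)
    pb <- random_walk_smooth(nb, t)
    sum(abs(pa - pb)) / denom
  }, 0)
  if (length(t_values) == 1) {
    return(dists[[1]])
  }
  # trapezoidal AUC over t, normalized by the t-range so the combined
  # distance keeps the per-t scale (and hence the [0, 2] range)
  auc <- sum(diff(t_values) * (utils::head(dists, -1) + utils::tail(dists, -1)) / 2)
  auc / (max(t_values) - min(t_values))
}

#' Random-walk reproducibility score
#'
#' `1 - disco_distance(a, b, t_values)`, after matching coverage: when the
#' totals differ the deeper map is first downsampled to the other's total
#' (uniformly, without replacement). The score lies in \[-1, 1\], with 1 at
#' identity and -1 for mutually exclusive contact sets.
#'
#' @param a,b raw `ContactMatrix` objects of identical shape.
#' @param t_values walk lengths (default 3).
#' @param seed seed for the coverage-matching downsample.
#' @return a single score in \[-1, 1\].
#' @export
disco_score <- function(a, b, t_values = 3, seed = NULL) {
  validate_contact_matrix(a)
  validate_contact_matrix(b)
  na_ <- total_interactions(a)
  nb_ <- total_interactions(b)
  if (na_ > nb_) {
    a <- downsample(a, nb_, seed = seed)
  } else if (nb_ > na_) {
    b <- downsample(b, na_, seed = seed)
  }
  d <- disco_distance(a, b, t_values)
  if (is.na(d)) {
    return(NA_real_)
  }
  1 - d
}
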