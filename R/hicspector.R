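# Spectral reproducibility score: compare the leading eigenvectors of the
# normalized graph Laplacians of two contact maps. The first eigenvectors
# capture the basic structure of the map; later ones are essentially noise.

#' Normalized Laplacian decomposition of a contact map
#'
#' Restricts the map to bins with non-zero degree, forms the Laplacian
#' `L = D - W` (D the diagonal degree matrix `D_ii = sum_j W_ij`),
#' normalizes as `D^{-1/2} L D^{-1/2}`, and eigendecomposes. Eigenvalues
#' are returned in ascending order (all within \[0, 2\] for a normalized
#' Laplacian); eigenvectors have unit norm and a deterministic sign (the
#' component of largest absolute value is made positive, first such
#' component on ties).
#'
#' @param m a `ContactMatrix`.
#' @return an object of class `SpectralDecomposition`: list with `support`
#'   (indices of retained bins), `L_norm`, `values`, `vectors` (columns in
#'   ascending eigenvalue order), or `NULL`-support error when no bin has
#'   positive degree.
#' @export
normalized_laplacian <- function(m) {
  validate_contact_matrix(m)
  deg <- rowSums(m$counts)
  support <- which(deg > 0)
  if (length(support) == 0) {
    stop("empty support: no bin has positive degree", call. = FALSE)
  }
  w <- m$counts[support, support, drop = FALSE]
  d <- rowSums(w)
  l <- diag(d) - w
  inv_sqrt <- 1 / sqrt(d)
  l_norm <- l * outer(inv_sqrt, inv_sqrt)
  eig <- eigen(l_norm, symmetric = TRUE)
  ord <- order(eig$values) # ascending
  vec <- eig$vectors[, ord, drop = FALSE]
  for (i in seq_len(ncol(vec))) {
    pivot <- which.max(abs(vec[, i]))
    if (vec[pivot, i] < 0) vec[, i] <- -vec[, i]
  }
  structure(
    list(support = support, L_norm = l_norm,
         values = eig$values[ord], vectors = vec),
    class = "SpectralDecomposition"
  )
}

#' Leading eigenvectors of a spectral decomposition
#'
#' The r eigenvectors with the smallest eigenvalues of the normalized
#' Laplacian, ascending, unit norm, deterministic sign.
#'
#' @param sd_obj a [normalized_laplacian()] decomposition.
#' @param r number of leading eigenvectors.
#' @return matrix with r columns.
#' @export
leading_eigenvectors <- function(sd_obj, r) {
  if (!inherits(sd_obj, "SpectralDecomposition")) {
    stop("sd_obj must be a SpectralDecomposition", call. = FALSE)
  }
  if (r > length(sd_obj$support)) {
    stop("r exceeds the support size", call. = FALSE)
  }
  sd_obj$vectors[, seq_len(r), drop = FALSE]
}

#' Spectral eigenvector distance between two contact maps
#'
#' `S_d(A, B) = sum_{i=0}^{r-1} ||v_i^A - v_i^B||` (Euclidean norm), with
#' eigenvectors paired by ascending eigenvalue index on the common support
#' (bins with non-zero degree in both maps). Because the sign of an
#' eigenvector is arbitrary, each pair is aligned by taking
#' `min(||v^A - v^B||, ||v^A + v^B||)`; each term is then at most
#' `sqrt(2)` for unit vectors.
#'
#' @param a,b `ContactMatrix` objects of identical shape.
#' @param r number of leading eigenvectors (default 20).
#' @return the distance `S_d >= 0`.
#' @export
spector_distance <- function(a, b, r = 20) {
  validate_contact_matrix(a)
  validate_contact_matrix(b)
  if (a$n_bins != b$n_bins) stop("a and b must have the same shape", call. = FALSE)
  keep <- rowSums(a$counts) > 0 & rowSums(b$counts) > 0
  if (sum(keep) < r) {
    stop(sprintf("common support (%d bins) smaller than r = %d", sum(keep), r),
         call. = FALSE)
  }
  sub <- function(m) contact_matrix(m$counts[keep, keep, drop = FALSE],
                                    m$resolution, chrom = m$chrom,
                                    is_raw = m$is_raw)
  da <- normalized_laplacian(sub(a))
  db <- normalized_laplacian(sub(b))
  # zero-degree bins can reappear inside the common support when a bin's
  # only contacts lie outside it; decompose on the intersection of the two
  # decompositions' supports
  common <- intersect(da$support, db$support)
  va <- da$vectors[match(common, da$support), seq_len(r), drop = FALSE]
  vb <- db$vectors[match(common, db$support), seq_len(r), drop = FALSE]
  sum(vapply(seq_len(r), function(i) {
    min(sqrt(sum((va[, i] - vb[, i])^2)), sqrt(sum((va[, i] + vb[, i])^2)))
  }, 0))
}

#' Spectral reproducibility score
#'
#' Linearly rescales the eigenvector distance to \[0, 1\]:
#' `score = 1 - S_d / (r * sqrt(2))`, clipped to \[0, 1\]. With sign-aligned
#' unit eigenvectors each distance term is at most `sqrt(2)`, so the map
#' hits the full range; identical maps score exactly 1.
#'
#' @inheritParams spector_distance
#' @return a score in \[0, 1\].
#' @export
spector_score <- function(a, b, r = 20) {
  s_d <- spector_distance(a, b, r)
  min(1, max(0, 1 - s_d / (r * sqrt(2))))
}
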