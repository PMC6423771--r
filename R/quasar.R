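# QuASAR: quality assessment of spatial arrangement reproducibility. As the
# 3D distance between two loci approaches zero, the correlation between
# their matrix rows approaches one; QuASAR exploits this by computing an
# interaction-correlation matrix within a 100-bin band of the diagonal,
# weighted by interaction enrichment over the distance-decay background.
# The pair score (QuASAR-Rep) correlates two samples' weighted correlation
# matrices; the single-sample quality score (QuASAR-QC) is the weighted
# minus the unweighted mean correlation, pooled across chromosomes.

#' Band filter for the QuASAR transform
#'
#' Removes rows/columns until every remaining bin has at least one
#' non-zero entry within `window` bins up- or downstream of the diagonal
#' among the remaining bins (iterated to a fixpoint, so filtering is
#' idempotent). Bin coordinates are preserved: downstream operations use
#' the mask, keeping inter-bin distances in original units.
#'
#' @param m a `ContactMatrix`.
#' @param window band half-width in bins (default 100).
#' @return list with `matrix` (the `ContactMatrix` restricted to retained
#'   bins) and `valid_mask` (logical over original bins).
#' @export
filter_bins <- function(m, window = 100) {
  validate_contact_matrix(m)
  n <- m$n_bins
  valid <- rep(TRUE, n)
  repeat {
    drop_any <- FALSE
    idx <- which(valid)
    for (i in idx) {
      lo <- max(1, i - window); hi <- min(n, i + window)
      js <- lo:hi
      js <- js[js != i & valid[js]]
      if (length(js) == 0 || all(m$counts[i, js] == 0)) {
        valid[i] <- FALSE
        drop_any <- TRUE
      }
    }
    if (!drop_any) break
  }
  if (!any(valid)) {
    return(list(matrix = NULL, valid_mask = valid))
  }
  sub <- contact_matrix(m$counts[valid, valid, drop = FALSE], m$resolution,
                        chrom = m$chrom, is_raw = m$is_raw)
  list(matrix = sub, valid_mask = valid)
}

#' Background signal-distance relationship
#'
#' Mean count per inter-bin distance d = 1..window over pairs of retained
#' bins (zero counts included in the mean; each unordered pair counted
#' once). Distances with no retained pair are `NA`, not 0.
#'
#' @param m a `ContactMatrix`.
#' @param valid_mask logical mask of retained bins (default: all).
#' @param window band half-width in bins.
#' @return numeric vector `background` with `background[d]` the mean at
#'   distance d; length `window`.
#' @export
distance_background <- function(m, valid_mask = NULL, window = 100) {
  validate_contact_matrix(m)
  n <- m$n_bins
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  out <- rep(NA_real_, window)
  for (d in seq_len(min(window, n - 1))) {
    i <- seq_len(n - d)
    ok <- valid_mask[i] & valid_mask[i + d]
    if (any(ok)) {
      out[d] <- mean(m$counts[cbind(i[ok], i[ok] + d)])
    }
  }
  out
}

#' QuASAR transform of one contact matrix
#'
#' Filters bins ([filter_bins()]), estimates the distance background,
#' forms the log-enrichment matrix (counts divided by background;
#' zero-count cells have undefined log enrichment and are excluded), and
#' computes the banded interaction-correlation matrix: for each retained
#' row pair (A, B) within `window` bins, the Pearson correlation of the
#' two rows' log enrichments over columns within `window` bins of both,
#' excluding the diagonal cells of either row and filtered columns.
#' Entries with fewer than 3 shared columns or zero variance are invalid.
#' The interaction weight at (A, B) is `sqrt(enrichment + 1)` (>= 1 on
#' valid entries).
#'
#' @param m a raw `ContactMatrix`.
#' @param window band half-width in bins (default 100, at any resolution).
#' @param valid_mask optional externally imposed bin mask (used by
#'   [quasar_rep()] to restrict both samples to a common bin set); the
#'   band filter is applied on top of it.
#' @return an object of class `QuasarTransform`: list with `valid_mask`,
#'   `background`, `corr` and `weights` (upper-band matrices, `NA` at
#'   invalid entries), `window`, `n_bins`; or `NULL` when every bin is
#'   filtered out.
#' @export
quasar_transform <- function(m, window = 100, valid_mask = NULL) {
  validate_contact_matrix(m)
  n <- m$n_bins
  if (!is.null(valid_mask)) {
    stopifnot(length(valid_mask) == n)
    work <- m$counts
    work[!valid_mask, ] <- 0
    work[, !valid_mask] <- 0
    m <- contact_matrix(work, m$resolution, chrom = m$chrom, is_raw = m$is_raw)
  }
  flt <- filter_bins(m, window)
  if (!any(flt$valid_mask)) {
    return(NULL)
  }
  mask <- flt$valid_mask
  bg <- distance_background(m, mask, window)
  res <- quasar_corr_cpp(m$counts, mask, c(NA_real_, bg), as.integer(window))
  structure(
    list(valid_mask = mask, background = bg, corr = res$corr,
         weights = res$weight, window = window, n_bins = n),
    class = "QuasarTransform"
  )
}

# weighted and unweighted correlation sums of one transform
quasar_sums <- function(qt) {
  ok <- !is.na(qt$corr)
  list(wsum = sum(qt$corr[ok] * qt$weights[ok]),
       w = sum(qt$weights[ok]),
       csum = sum(qt$corr[ok]),
       n = sum(ok))
}

#' QuASAR replicate score for a pair of samples
#'
#' Restricts both matrices to the intersection of their filtered bin
#' sets, recomputes the transform of each on that common set, forms each
#' sample's weighted correlation matrix (elementwise
#' `corr * weights / sum(valid weights)`), and returns the Pearson
#' correlation of the two weighted matrices over jointly valid entries.
#'
#' @param a,b raw `ContactMatrix` objects of identical shape (one
#'   chromosome).
#' @param window band half-width in bins.
#' @return a score in \[-1, 1\]; `NA` with a warning when undefined.
#' @export
quasar_rep <- function(a, b, window = 100) {
  validate_contact_matrix(a)
  validate_contact_matrix(b)
  if (a$n_bins != b$n_bins) stop("a and b must have the same shape", call. = FALSE)
  fa <- filter_bins(a, window)
  fb <- filter_bins(b, window)
  common <- fa$valid_mask & fb$valid_mask
  if (!any(common)) {
    return(undefined_score("no bin survives filtering in both samples"))
  }
  qa <- quasar_transform(a, window, valid_mask = common)
  qb <- quasar_transform(b, window, valid_mask = common)
  if (is.null(qa) || is.null(qb)) {
    return(undefined_score("a sample lost all bins on the common set"))
  }
  ok <- !is.na(qa$corr) & !is.na(qb$corr)
  if (sum(ok) < 3) {
    return(undefined_score("fewer than 3 jointly valid correlation entries"))
  }
  wa <- qa$corr[ok] * qa$weights[ok] / sum(qa$weights[!is.na(qa$corr)])
  wb <- qb$corr[ok] * qb$weights[ok] / sum(qb$weights[!is.na(qb$corr)])
  if (stats::sd(wa) == 0 || stats::sd(wb) == 0) {
    return(undefined_score("constant weighted correlation matrix"))
  }
  stats::cor(wa, wb)
}

#' QuASAR quality score for a single sample
#'
#' Quality is the weighted mean correlation minus the unweighted mean
#' correlation. In a structureless (random-ligation-like) matrix,
#' enrichment and row correlation are uncoupled and the two means agree
#' (QC near 0); genuine 3D structure couples enriched entries with
#' correlated rows, pushing the weighted mean above the unweighted one
#' (QC > 0). Noise lowers QC monotonically.
#'
#' @param matrices a `ContactMatrix` or list of per-chromosome
#'   `ContactMatrix` objects.
#' @param window band half-width in bins.
#' @param pooled if `TRUE` (default), numerators and denominators are
#'   pooled over chromosome matrix cells before dividing; if `FALSE` the
#'   per-chromosome QC values are averaged instead.
#' @return a single quality score; `NA` with a warning when undefined.
#' @export
quasar_qc <- function(matrices, window = 100, pooled = TRUE) {
  if (inherits(matrices, "ContactMatrix")) matrices <- list(matrices)
  sums <- list()
  for (m in matrices) {
    qt <- quasar_transform(m, window)
    if (!is.null(qt)) {
      s <- quasar_sums(qt)
      if (s$n > 0) sums[[length(sums) + 1L]] <- s
    }
  }
  if (length(sums) == 0) {
    return(undefined_score("no chromosome yields valid correlation entries"))
  }
  if (pooled) {
    wsum <- sum(vapply(sums, `[[`, 0, "wsum"))
    w <- sum(vapply(sums, `[[`, 0, "w"))
    csum <- sum(vapply(sums, `[[`, 0, "csum"))
    n <- sum(vapply(sums, `[[`, 0, "n"))
    wsum / w - csum / n
  } else {
    mean(vapply(sums, function(s) s$wsum / s$w - s$csum / s$n, 0))
  }
}
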