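# Score aggregation, empirical thresholds and the ranking experiments that
# tie the method modules together.

#' Score a pair of contact matrices with a named method
#'
#' Thin dispatcher over the four reproducibility scores.
#'
#' @param a,b raw `ContactMatrix` objects of identical shape.
#' @param method one of `"hicrep"`, `"genomedisco"`, `"hicspector"`,
#'   `"quasar-rep"`.
#' @param h,max_distance_bins SCC parameters (see [scc()]).
#' @param t_values random-walk lengths (see [disco_score()]).
#' @param r number of leading eigenvectors (see [spector_score()]).
#' @param window QuASAR band half-width (see [quasar_rep()]).
#' @param seed seed for the coverage-matching downsample in
#'   `"genomedisco"`.
#' @return a single score.
#' @export
score_pair <- function(a, b,
                       method = c("hicrep", "genomedisco", "hicspector",
                                  "quasar-rep"),
                       h = default_h(a$resolution),
                       max_distance_bins = default_max_distance_bins(a$resolution),
                       t_values = 3, r = 20, window = 100, seed = NULL) {
  method <- match.arg(method)
  switch(method,
         "hicrep" = scc(a, b, h = h, max_distance_bins = max_distance_bins),
         "genomedisco" = disco_score(a, b, t_values = t_values, seed = seed),
         "hicspector" = spector_score(a, b, r = r),
         "quasar-rep" = quasar_rep(a, b, window = window))
}

#' Genome-level score from per-chromosome scores
#'
#' The reproducibility score of a pair of experiments is the arithmetic
#' mean of the per-chromosome scores. Undefined chromosomes (`NA`) are
#' excluded from the mean with a warning rather than treated as zero.
#'
#' @param per_chromosome named numeric vector of per-chromosome scores,
#'   possibly containing `NA`.
#' @return the mean over defined scores; `NA` with a warning if all are
#'   undefined.
#' @export
genome_score <- function(per_chromosome) {
  if (length(per_chromosome) == 0) {
    stop("at least one chromosome score is required", call. = FALSE)
  }
  bad <- is.na(per_chromosome)
  if (all(bad)) {
    return(undefined_score("all chromosome scores are undefined"))
  }
  if (any(bad)) {
    warning(sprintf("%d undefined chromosome score(s) excluded from the mean",
                    sum(bad)), call. = FALSE)
  }
  mean(per_chromosome[!bad])
}

#' Empirical reproducibility threshold
#'
#' Analogous to a maximal-margin hyperplane in one dimension: the midpoint
#' between the highest-scoring non-replicate pair and the lowest-scoring
#' biological replicate pair. A negative margin flags overlapping score
#' distributions, i.e. the method cannot separate the two classes at this
#' coverage.
#'
#' @param nonrep_scores scores of non-replicate pairs.
#' @param biorep_scores scores of biological replicate pairs.
#' @return list with `threshold = (max(nonrep) + min(biorep)) / 2` and
#'   `margin = min(biorep) - max(nonrep)`.
#' @export
empirical_threshold <- function(nonrep_scores, biorep_scores) {
  nonrep_scores <- nonrep_scores[!is.na(nonrep_scores)]
  biorep_scores <- biorep_scores[!is.na(biorep_scores)]
  if (length(nonrep_scores) == 0 || length(biorep_scores) == 0) {
    stop("both score lists must be non-empty", call. = FALSE)
  }
  hi_non <- max(nonrep_scores)
  lo_bio <- min(biorep_scores)
  list(threshold = (hi_non + lo_bio) / 2, margin = lo_bio - hi_non)
}

#' Score every pair of a benchmark and evaluate the replicate-type ranking
#'
#' Scores all labelled pairs of a [make_benchmark()] set with one method,
#' then reports: the fraction of (biological, non-replicate) score pairs
#' correctly ordered (biological higher); whether
#' pseudo >= biological >= non-replicate holds within each cell type
#' (non-replicate scores of a type are those of its cross pairs); the
#' one-sided Kolmogorov-Smirnov statistic and p-value for biological
#' scores stochastically dominating non-replicate scores; and the
#' empirical threshold.
#'
#' @param bench a `BenchmarkSet`.
#' @param method method name passed to [score_pair()].
#' @param ... further parameters for [score_pair()].
#' @param seed seed forwarded to coverage matching.
#' @return list with `scores` (the pair table plus a `score` column),
#'   `ordering_accuracy`, `type_ordering` (named logical per type),
#'   `ks` (list statistic/p.value), `threshold` (list from
#'   [empirical_threshold()]).
#' @export
ranking_evaluation <- function(bench, method, ..., seed = NULL) {
  if (!inherits(bench, "BenchmarkSet")) {
    stop("bench must be a BenchmarkSet", call. = FALSE)
  }
  pairs <- bench$pairs
  if (is.null(pairs$label)) stop("pairs table lacks labels", call. = FALSE)
  seeds <- split_seed(seed, nrow(pairs))
  pairs$score <- vapply(seq_len(nrow(pairs)), function(i) {
    score_pair(bench$matrices[[pairs$a[i]]], bench$matrices[[pairs$b[i]]],
               method = method, ..., seed = seeds[[i]])
  }, 0)
  bio <- pairs$score[pairs$label == "biological"]
  non <- pairs$score[pairs$label == "non_replicate"]
  acc <- mean(outer(bio, non, ">"))
  types <- unique(pairs$cell_type_a[pairs$label != "non_replicate"])
  type_ord <- vapply(types, function(tp) {
    ps <- pairs$score[pairs$label == "pseudo" & pairs$cell_type_a == tp]
    bs <- pairs$score[pairs$label == "biological" & pairs$cell_type_a == tp]
    ns <- pairs$score[pairs$label == "non_replicate" &
                        (pairs$cell_type_a == tp | pairs$cell_type_b == tp)]
    min(ps) >= max(bs) && min(bs) >= max(ns)
  }, TRUE)
  ks <- suppressWarnings(
    stats::ks.test(bio, non, alternative = "less")
  )
  list(scores = pairs,
       ordering_accuracy = acc,
       type_ordering = type_ord,
       ks = list(statistic = unname(ks$statistic), p.value = ks$p.value),
       threshold = empirical_threshold(non, bio))
}

#' Noise-response curve of a score
#'
#' Builds a noise ladder from `m`, scores each ladder member against a
#' noise-free reference resample of `m`, and returns the per-level scores.
#' For the single-sample method `"quasar-qc"` the ladder member itself is
#' scored. Increasing the injected noise level should always decrease the
#' score.
#'
#' @param m raw `ContactMatrix`.
#' @param method a [score_pair()] method or `"quasar-qc"`.
#' @param levels noise fractions (default 0, 5, ..., 50 percent).
#' @param g_share fraction of noise from the genomic-distance matrix G.
#' @param seed integer master seed.
#' @param ... further method parameters.
#' @return data.frame with columns `level` and `score`.
#' @export
noise_response_curve <- function(m, method,
                                 levels = c(0, .05, .10, .15, .20, .30, .40, .50),
                                 g_share = 1 / 3, seed = NULL, ...) {
  seeds <- split_seed(seed, 2 + length(levels))
  ladder <- noise_ladder(m, levels = levels, g_share = g_share,
                         seed = seeds[[1]])
  if (method == "quasar-qc") {
    scores <- vapply(ladder, function(x) quasar_qc(x, ...), 0)
  } else {
    ref <- mix_matrices(m,
                        G = m, R = m, # unused at noise_fraction = 0
                        c_total = total_interactions(m),
                        noise_fraction = 0, seed = seeds[[2]])
    scores <- vapply(seq_along(ladder), function(i) {
      score_pair(ref, ladder[[i]], method = method, ...,
                 seed = seeds[[2 + i]])
    }, 0)
  }
  data.frame(level = levels, score = unname(scores))
}
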