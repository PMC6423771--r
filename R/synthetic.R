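#' Simulate the ground-truth contact intensity of a cell type
#'
#' Builds a noise-free intensity surface lambda(i, j) for one chromosome as
#' a product of the features reproducibility scores are sensitive to:
#'
#' * a power-law genomic distance decay `(|i - j| + 1)^decay_exponent`,
#' * contiguous TAD blocks whose internal contacts are multiplied by
#'   `tad_enrichment`,
#' * an A/B compartment checkerboard: pairs sharing a compartment label and
#'   not lying in the same TAD are multiplied by `compartment_enrichment`,
#' * a per-bin multiplicative bias (lognormal with `sdlog = bias_spread`)
#'   standing in for GC content and mappability.
#'
#' Distinct cell types are emulated by drawing different TAD boundaries and
#' compartment labels (different seeds).
#'
#' @param n_bins number of bins (>= 10).
#' @param decay_exponent power-law slope of the distance decay; must be
#'   negative. Default -1, the classic contact-probability scaling.
#' @param n_tads number of TADs; 0 disables domain structure.
#' @param tad_enrichment fold enrichment of within-TAD contacts.
#' @param compartment_enrichment fold enrichment of same-compartment,
#'   cross-TAD contacts; 1 disables compartments.
#' @param bias_spread lognormal sdlog of per-bin bias; 0 disables bias.
#' @param seed integer seed; the ground truth is deterministic given it.
#' @return an object of class `SyntheticGroundTruth` with fields `n_bins`,
#'   `decay_exponent`, `tad_boundaries`, `tad_enrichment`,
#'   `compartment_labels`, `compartment_enrichment`, `bias`, `lambda`
#'   (symmetric positive intensity matrix).
#' @export
simulate_cell_type <- function(n_bins, decay_exponent = -1, n_tads = 10,
                               tad_enrichment = 3,
                               compartment_enrichment = 1.5,
                               bias_spread = 0.3, seed = NULL) {
  if (n_bins < 10) stop("n_bins must be at least 10", call. = FALSE)
  if (decay_exponent >= 0) stop("decay_exponent must be negative", call. = FALSE)
  if (n_tads < 0 || tad_enrichment <= 0 || compartment_enrichment <= 0 ||
      bias_spread < 0) {
    stop("invalid generator parameter", call. = FALSE)
  }
  drawn <- with_seed(seed, {
    boundaries <- if (n_tads > 0) {
      sort(sample(seq_len(n_bins - 1), n_tads))
    } else {
      integer()
    }
    # compartments: alternating A/B blocks with random block lengths around
    # n_bins / 8 bins, giving a plaid pattern at the scale real maps show
    n_blocks <- max(2L, round(n_bins / 8 / 5)) * 4L
    lens <- pmax(1L, stats::rpois(n_blocks, n_bins / n_blocks))
    labels <- rep(rep(c("A", "B"), length.out = n_blocks), times = lens)
    labels <- rep(labels, length.out = n_bins)
    bias <- if (bias_spread > 0) {
      stats::rlnorm(n_bins, meanlog = 0, sdlog = bias_spread)
    } else {
      rep(1, n_bins)
    }
    list(boundaries = boundaries, labels = labels, bias = bias)
  })
  tad_id <- findInterval(seq_len(n_bins) - 1L, drawn$boundaries)
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  lambda <- (d + 1)^decay_exponent
  same_tad <- outer(tad_id, tad_id, "==")
  lambda[same_tad] <- lambda[same_tad] * tad_enrichment
  same_comp <- outer(drawn$labels, drawn$labels, "==")
  long <- same_comp & !same_tad
  lambda[long] <- lambda[long] * compartment_enrichment
  lambda <- lambda * outer(drawn$bias, drawn$bias)
  structure(
    list(n_bins = as.integer(n_bins), decay_exponent = decay_exponent,
         tad_boundaries = drawn$boundaries, tad_enrichment = tad_enrichment,
         compartment_labels = drawn$labels,
         compartment_enrichment = compartment_enrichment,
         bias = drawn$bias, lambda = lambda),
    class = "SyntheticGroundTruth"
  )
}

#' @export
print.SyntheticGroundTruth <- function(x, ...) {
  cat(sprintf("SyntheticGroundTruth: %d bins, decay %g, %d TADs, %d/%d A/B bins\n",
              x$n_bins, x$decay_exponent, length(x$tad_boundaries),
              sum(x$compartment_labels == "A"),
              sum(x$compartment_labels == "B")))
  invisible(x)
}

#' Sample a sequencing replicate from a ground truth
#'
#' Draws `n_interactions` unordered bin pairs from the multinomial
#' distribution with probabilities proportional to the intensity surface
#' (off-diagonal pairs carry weight `2 * lambda[i, j]`, matching a
#' symmetric intensity over ordered pairs) and bins them into a raw contact
#' matrix. The total is conserved exactly.
#'
#' @param gt a [simulate_cell_type()] ground truth.
#' @param n_interactions number of interactions to draw.
#' @param seed integer seed.
#' @param resolution bin width in bp recorded on the output (default 40000).
#' @param chrom chromosome label for the output.
#' @param bias_jitter lognormal sdlog of an extra per-bin bias factor drawn
#'   for this replicate only; 0 (default) reproduces the ground truth
#'   exactly up to sampling noise. Biological replicates use a small
#'   positive value so that they differ by more than resampling alone.
#' @return a raw `ContactMatrix`.
#' @export
sample_replicate <- function(gt, n_interactions, seed = NULL,
                             resolution = 40000, chrom = "chr1",
                             bias_jitter = 0) {
  if (!inherits(gt, "SyntheticGroundTruth")) {
    stop("gt must be a SyntheticGroundTruth", call. = FALSE)
  }
  if (n_interactions < 0) stop("n_interactions must be >= 0", call. = FALSE)
  n <- gt$n_bins
  counts <- with_seed(seed, {
    lambda <- gt$lambda
    if (bias_jitter > 0) {
      j <- stats::rlnorm(n, 0, bias_jitter)
      lambda <- lambda * outer(j, j)
    }
    w <- 2 * lambda
    diag(w) <- diag(lambda)
    wu <- w[upper_cells(n)]
    if (n_interactions == 0) {
      numeric(length(wu))
    } else {
      as.numeric(stats::rmultinom(1, n_interactions, wu))
    }
  })
  contact_matrix(symmetrize_upper(counts, n), resolution, chrom = chrom,
                 is_raw = TRUE)
}

#' Build a labelled synthetic benchmark of replicate pairs
#'
#' Generates `n_cell_types` distinct ground truths (different TAD
#' boundaries, compartments and biases), samples `reps_per_type` biological
#' replicates per type (each with a small per-replicate bias jitter, so
#' their variation exceeds pure resampling), and labels every within-type
#' pair `biological`, every cross-type pair `non_replicate`, plus one
#' `pseudo` pair per type built by pooling the first two replicates and
#' resampling (see [pseudo_replicates()]).
#'
#' @param n_cell_types number of distinct cell types (>= 2).
#' @param reps_per_type biological replicates per type (>= 2).
#' @param n_interactions coverage per replicate.
#' @param n_bins bins per matrix.
#' @param seed master seed driving all draws.
#' @param bias_jitter per-replicate lognormal bias sdlog (default 0.05).
#' @param ... further arguments to [simulate_cell_type()].
#' @return an object of class `BenchmarkSet`: list with `matrices` (named
#'   list of `ContactMatrix`), `pairs` (data.frame with columns `a`, `b`,
#'   `label`, `cell_type_a`, `cell_type_b`, `coverage`), `ground_truths`,
#'   and `seed`.
#' @export
make_benchmark <- function(n_cell_types = 4, reps_per_type = 2,
                           n_interactions = 5e6, n_bins = 500, seed = NULL,
                           bias_jitter = 0.05, ...) {
  if (n_cell_types < 2) stop("n_cell_types must be >= 2", call. = FALSE)
  if (reps_per_type < 2) stop("reps_per_type must be >= 2", call. = FALSE)
  seeds <- split_seed(seed, n_cell_types * (reps_per_type + 2))
  mats <- list()
  gts <- list()
  meta <- list()
  si <- 1L
  for (ct in seq_len(n_cell_types)) {
    type <- sprintf("type%d", ct)
    gts[[type]] <- simulate_cell_type(n_bins, seed = seeds[[si]], ...)
    si <- si + 1L
    for (r in seq_len(reps_per_type)) {
      nm <- sprintf("%s_rep%d", type, r)
      mats[[nm]] <- sample_replicate(gts[[type]], n_interactions,
                                     seed = seeds[[si]],
                                     bias_jitter = bias_jitter)
      meta[[nm]] <- type
      si <- si + 1L
    }
    ps <- pseudo_replicates(mats[[sprintf("%s_rep1", type)]],
                            mats[[sprintf("%s_rep2", type)]],
                            seed = seeds[[si]])
    si <- si + 1L
    mats[[sprintf("%s_pseudo1", type)]] <- ps[[1]]
    mats[[sprintf("%s_pseudo2", type)]] <- ps[[2]]
  }
  pairs <- list()
  add_pair <- function(a, b, label, ta, tb) {
    cov <- (total_interactions(mats[[a]]) + total_interactions(mats[[b]])) / 2
    pairs[[length(pairs) + 1L]] <<- data.frame(
      a = a, b = b, label = label, cell_type_a = ta, cell_type_b = tb,
      coverage = cov, stringsAsFactors = FALSE)
  }
  reps <- names(meta)
  for (ct in seq_len(n_cell_types)) {
    type <- sprintf("type%d", ct)
    members <- reps[unlist(meta) == type]
    cmb <- utils::combn(members, 2)
    for (k in seq_len(ncol(cmb))) {
      add_pair(cmb[1, k], cmb[2, k], "biological", type, type)
    }
    add_pair(sprintf("%s_pseudo1", type), sprintf("%s_pseudo2", type),
             "pseudo", type, type)
  }
  for (c1 in seq_len(n_cell_types - 1)) {
    for (c2 in seq(c1 + 1, n_cell_types)) {
      t1 <- sprintf("type%d", c1); t2 <- sprintf("type%d", c2)
      for (a in reps[unlist(meta) == t1]) {
        for (b in reps[unlist(meta) == t2]) {
          add_pair(a, b, "non_replicate", t1, t2)
        }
      }
    }
  }
  structure(
    list(matrices = mats, pairs = do.call(rbind, pairs),
         ground_truths = gts, seed = seed),
    class = "BenchmarkSet"
  )
}

#' @export
print.BenchmarkSet <- function(x, ...) {
  tab <- table(x$pairs$label)
  cat(sprintf("BenchmarkSet: %d matrices, %d pairs (%s)\n",
              length(x$matrices), nrow(x$pairs),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
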