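# Noise model for Hi-C contact maps: two "pure noise" matrices derived from
# a real matrix -- one preserving only the genomic distance effect (G), one
# modelling random ligation of non-crosslinked fragments (R) -- mixed with
# the real matrix at chosen proportions.

#' Genomic-distance-effect noise matrix
#'
#' Shuffles the entries of `m` within each genomic distance, which preserves
#' the distance decay exactly while destroying domain and compartment
#' structure. To retain GC/mappability bias, the shuffle is stratified: at
#' each bin offset D the cells (i, i+D) are ordered by the product of the
#' marginals of bins i and i+D, cut into consecutive strata of
#' `stratum_size` elements (the last stratum may be smaller), and values are
#' permuted only within their stratum. Per-offset sums are therefore
#' conserved exactly.
#'
#' @param m raw `ContactMatrix`.
#' @param stratum_size number of cells per stratum (default 100).
#' @param seed integer seed; output is deterministic given it.
#' @return a raw `ContactMatrix` G of the same shape and total as `m`.
#' @export
genomic_distance_noise <- function(m, stratum_size = 100, seed = NULL) {
  validate_contact_matrix(m)
  if (!m$is_raw) stop("genomic_distance_noise needs a raw matrix", call. = FALSE)
  if (stratum_size < 1) stop("stratum_size must be >= 1", call. = FALSE)
  n <- m$n_bins
  marg <- rowSums(m$counts)
  out <- matrix(0, n, n)
  with_seed(seed, {
    for (D in 0:(n - 1)) {
      i <- seq_len(n - D)
      k <- i + D
      vals <- m$counts[cbind(i, k)]
      prod <- marg[i] * marg[k]
      ord <- order(prod)
      shuffled <- vals
      n_cells <- length(vals)
      starts <- seq(1, n_cells, by = stratum_size)
      for (s in starts) {
        grp <- ord[s:min(s + stratum_size - 1, n_cells)]
        if (length(grp) > 1) {
          shuffled[grp] <- vals[sample(grp)]
        }
      }
      out[cbind(i, k)] <- shuffled
      out[cbind(k, i)] <- shuffled
    }
  })
  contact_matrix(out, m$resolution, chrom = m$chrom, is_raw = TRUE)
}

#' Random-ligation noise matrix
#'
#' Simulates spurious contacts from ligation of non-crosslinked fragments:
#' N independent bin pairs (i, k) are drawn, each endpoint independently
#' with probability proportional to its marginal in `m` (modelling per-bin
#' GC/mappability bias), where N is the total number of interactions in
#' `m`. The total is conserved exactly; a bin with zero marginal is never
#' sampled.
#'
#' @param m raw `ContactMatrix` with at least one interaction.
#' @param seed integer seed.
#' @return a raw `ContactMatrix` R with `total_interactions(R) == N`.
#' @export
random_ligation_noise <- function(m, seed = NULL) {
  validate_contact_matrix(m)
  if (!m$is_raw) stop("random_ligation_noise needs a raw matrix", call. = FALSE)
  n_total <- total_interactions(m)
  if (n_total <= 0) {
    stop("all-zero matrix: no marginal distribution to sample from",
         call. = FALSE)
  }
  n <- m$n_bins
  p <- rowSums(m$counts)
  out <- with_seed(seed, {
    i <- sample.int(n, n_total, replace = TRUE, prob = p)
    k <- sample.int(n, n_total, replace = TRUE, prob = p)
    lo <- pmin(i, k); hi <- pmax(i, k)
    # tally unordered pairs via their upper-triangle linear cell id
    id <- (hi - 1) * n + lo
    tab <- tabulate(id, nbins = n * n)
    cm <- matrix(tab, n, n)
    cm + t(cm) - diag(diag(cm))
  })
  contact_matrix(out, m$resolution, chrom = m$chrom, is_raw = TRUE)
}

#' Mix a real matrix with its two noise matrices
#'
#' Builds a simulated noisy matrix with exactly `c_total` interactions by
#' sampling counts uniformly at random, without replacement, from the real
#' matrix and the two noise matrices at a target ratio:
#' `round(c_total * (1 - noise_fraction))` interactions from `m`,
#' `round(c_total * noise_fraction * g_share)` from `G`, and the remainder
#' from `R` (largest-remainder rounding, so the three source counts sum to
#' `c_total` exactly).
#'
#' @param m,G,R raw `ContactMatrix` objects of identical shape.
#' @param c_total target total interaction count.
#' @param noise_fraction proportion of counts taken from noise, in \[0, 1\].
#' @param g_share fraction of the noise taken from G (the study used 1/3
#'   and 2/3), in \[0, 1\].
#' @param seed integer seed.
#' @return a raw `ContactMatrix` with `total_interactions == c_total`.
#' @export
mix_matrices <- function(m, G, R, c_total, noise_fraction, g_share = 1 / 3,
                         seed = NULL) {
  for (x in list(m, G, R)) validate_contact_matrix(x)
  if (m$n_bins != G$n_bins || m$n_bins != R$n_bins) {
    stop("m, G, R must have the same shape", call. = FALSE)
  }
  if (noise_fraction < 0 || noise_fraction > 1) {
    stop("noise_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (g_share < 0 || g_share > 1) stop("g_share must lie in [0, 1]", call. = FALSE)
  shares <- c(real = 1 - noise_fraction,
              G = noise_fraction * g_share,
              R = noise_fraction * (1 - g_share))
  take <- largest_remainder(c_total, shares)
  sources <- list(real = m, G = G, R = R)
  for (s in names(sources)) {
    avail <- total_interactions(sources[[s]])
    if (take[[s]] > avail) {
      stop(sprintf("source %s has %g interactions, %g requested",
                   s, avail, take[[s]]), call. = FALSE)
    }
  }
  n <- m$n_bins
  cells <- upper_cells(n)
  seeds <- split_seed(seed, 3)
  acc <- numeric(length(cells))
  for (s in seq_along(sources)) {
    if (take[s] > 0) {
      src <- sources[[s]]$counts[cells]
      acc <- acc + with_seed(seeds[[s]], sample_counts_wor(src, take[s]))
    }
  }
  contact_matrix(symmetrize_upper(acc, n), m$resolution, chrom = m$chrom,
                 is_raw = TRUE)
}

#' Noise ladder: one mixed matrix per noise level
#'
#' Generates G and R once from `m`, then mixes at each requested noise
#' fraction, keeping the total equal to `total_interactions(m)` throughout.
#' The default ladder is the study design 5, 10, 15, 20, 30, 40, 50
#' percent; level 0 (a pure resample of `m`) may be included to provide the
#' noise-free reference.
#'
#' @param m raw `ContactMatrix`.
#' @param levels noise fractions in \[0, 1\].
#' @param g_share fraction of noise from G.
#' @param seed integer seed; G and R realizations are shared across levels.
#' @return named list of `ContactMatrix`, one per level.
#' @export
noise_ladder <- function(m, levels = c(.05, .10, .15, .20, .30, .40, .50),
                         g_share = 1 / 3, seed = NULL) {
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]", call. = FALSE)
  seeds <- split_seed(seed, 2 + length(levels))
  G <- genomic_distance_noise(m, seed = seeds[[1]])
  R <- random_ligation_noise(m, seed = seeds[[2]])
  n_total <- total_interactions(m)
  out <- lapply(seq_along(levels), function(i) {
    mix_matrices(m, G, R, n_total, levels[i], g_share, seed = seeds[[2 + i]])
  })
  names(out) <- sprintf("noise_%g", levels)
  out
}
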