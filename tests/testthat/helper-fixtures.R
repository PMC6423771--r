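# Shared fixture builders: everything is generated in code, no files.

# symmetric random integer contact matrix
random_cm <- function(n, seed, resolution = 40000, max_count = 20,
                      density = 0.6) {
  set.seed(seed)
  cm <- matrix(0, n, n)
  ut <- upper.tri(cm, diag = TRUE)
  vals <- stats::rbinom(sum(ut), 1, density) * sample.int(max_count, sum(ut),
                                                          replace = TRUE)
  cm[ut] <- vals
  cm <- cm + t(cm)
  diag(cm) <- diag(cm) / 2
  contact_matrix(cm, resolution)
}

# the 4-node mutually-exclusive-contacts pair: A has edges 1-2 and 3-4,
# B has edges 1-3 and 2-4
disjoint_pair <- function() {
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- 1; a[3, 4] <- a[4, 3] <- 1
  b <- matrix(0, 4, 4); b[1, 3] <- b[3, 1] <- 1; b[2, 4] <- b[4, 2] <- 1
  list(a = contact_matrix(a, 40000), b = contact_matrix(b, 40000))
}

# small synthetic replicate used across method tests
small_replicate <- function(n_bins = 120, n = 2e5, seed = 7, ...) {
  gt <- simulate_cell_type(n_bins, seed = seed, ...)
  sample_replicate(gt, n, seed = seed + 1)
}

expect_cm_equal <- function(x, y) {
  expect_equal(x$counts, y$counts)
  expect_equal(x$resolution, y$resolution)
  expect_equal(x$chrom, y$chrom)
}
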