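test_that("genomic distance noise permutes within offsets and strata", {
  m <- random_cm(30, seed = 1)
  g <- genomic_distance_noise(m, seed = 2)
  expect_true(isSymmetric(g$counts))
  for (D in 0:29) {
    i <- seq_len(30 - D)
    expect_equal(sum(g$counts[cbind(i, i + D)]), sum(m$counts[cbind(i, i + D)]))
    # full per-offset multisets match (default stratum covers each offset)
    expect_equal(sort(g$counts[cbind(i, i + D)]), sort(m$counts[cbind(i, i + D)]))
  }
  expect_identical(genomic_distance_noise(m, seed = 2)$counts, g$counts)

  # a matrix constant within each offset is a fixed point
  offs <- abs(outer(1:20, 1:20, "-"))
  const <- contact_matrix(matrix(20 - offs, 20, 20), 40000)
  expect_identical(genomic_distance_noise(const, seed = 3)$counts, const$counts)

  # singleton strata forbid any movement
  expect_identical(genomic_distance_noise(m, stratum_size = 1, seed = 4)$counts,
                   m$counts)
})

test_that("genomic distance noise erases TAD contrast", {
  gt <- simulate_cell_type(100, n_tads = 5, tad_enrichment = 4,
                          compartment_enrichment = 1, bias_spread = 0,
                          seed = 6)
  m <- sample_replicate(gt, 5e5, seed = 7)
  g <- genomic_distance_noise(m, seed = 8)
  tad_id <- findInterval(0:99, gt$tad_boundaries)
  same <- outer(tad_id, tad_id, "==")
  offs <- abs(outer(1:100, 1:100, "-"))
  # per-offset within/between ratio removes the distance-decay confound
  contrast <- function(x) {
    mean(vapply(2:15, function(d) {
      mean(x$counts[same & offs == d]) / mean(x$counts[!same & offs == d])
    }, 0))
  }
  expect_gt(contrast(m), 1.5)
  expect_lt(abs(contrast(g) - 1), 0.15)
})

test_that("random ligation noise conserves totals and follows marginals", {
  m <- random_cm(20, seed = 3)
  r <- random_ligation_noise(m, seed = 4)
  expect_identical(total_interactions(r), total_interactions(m))
  expect_true(isSymmetric(r$counts))
  expect_error(random_ligation_noise(contact_matrix(matrix(0, 3, 3), 1)),
               "all-zero")

  # a zero-marginal bin is never sampled
  cm <- m$counts; cm[5, ] <- 0; cm[, 5] <- 0
  m0 <- contact_matrix(cm, 40000)
  r0 <- random_ligation_noise(m0, seed = 5)
  expect_true(all(r0$counts[5, ] == 0))

  # uniform marginals: ordered endpoints are i.i.d. uniform, so unordered
  # pair {i, k} has probability 2/n^2 off-diagonal and 1/n^2 on it
  n_bins <- 20
  flat2 <- contact_matrix(matrix(4762, n_bins, n_bins), 40000)
  r2 <- random_ligation_noise(flat2, seed = 7)
  n2 <- total_interactions(flat2)
  ut <- upper.tri(flat2$counts, diag = TRUE)
  p <- ifelse(row(flat2$counts) == col(flat2$counts), 1, 2)[ut] / n_bins^2
  z <- (r2$counts[ut] - n2 * p) / sqrt(n2 * p * (1 - p))
  expect_lt(max(abs(z)), 5)
  expect_gt(mean(abs(z) <= 3), 0.98)
})

test_that("mixtures hit exact source counts and totals", {
  # disjoint supports make the source of every count identifiable
  block <- function(shift) {
    cm <- matrix(0, 9, 9)
    idx <- shift + 1:3
    cm[idx, idx] <- 100
    contact_matrix(cm, 40000)
  }
  m <- block(0); g <- block(3); r <- block(6)
  mixed <- mix_matrices(m, g, r, c_total = 3e2, noise_fraction = 1,
                        g_share = 1 / 3, seed = 1)
  expect_identical(total_interactions(mixed), 300)
  expect_equal(sum(mixed$counts[4:6, 4:6][upper.tri(matrix(0, 3, 3), TRUE)]), 100)
  expect_equal(sum(mixed$counts[1:3, 1:3]), 0)

  # noise_fraction 0 is a uniform resample of m alone
  m2 <- random_cm(15, seed = 9)
  res <- mix_matrices(m2, m2, m2, c_total = total_interactions(m2),
                      noise_fraction = 0, seed = 2)
  expect_identical(res$counts, m2$counts) # drawing all interactions
  half <- mix_matrices(m2, m2, m2, c_total = 50, noise_fraction = 0, seed = 3)
  expect_true(all(half$counts <= m2$counts))
  expect_identical(
    mix_matrices(m2, m2, m2, 100, 0.5, seed = 11)$counts,
    mix_matrices(m2, m2, m2, 100, 0.5, seed = 11)$counts)
  expect_error(mix_matrices(m2, m2, m2, 1e9, 0.5, seed = 1), "requested")
})

test_that("noise ladders share realizations and conserve totals", {
  m <- small_replicate(n_bins = 60, n = 5e4)
  lad <- noise_ladder(m, seed = 5)
  expect_length(lad, 7)
  expect_true(all(vapply(lad, total_interactions, 0) == 5e4))
  single <- noise_ladder(m, levels = 0, seed = 5)
  expect_length(single, 1)
  expect_true(all(single[[1]]$counts <= m$counts))
})
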