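# window = 8 on small toys keeps the banded rules non-trivial (some column
# pairs fall outside the band) while staying brute-forceable.

# brute-force QuASAR transform oracle: independent reimplementation of the
# filtering, background, log-enrichment and banded-correlation rules
brute_quasar <- function(cm, window) {
  n <- nrow(cm)
  valid <- rep(TRUE, n)
  repeat {
    changed <- FALSE
    for (i in which(valid)) {
      js <- setdiff(max(1, i - window):min(n, i + window), i)
      js <- js[valid[js]]
      if (length(js) == 0 || all(cm[i, js] == 0)) {
        valid[i] <- FALSE; changed <- TRUE
      }
    }
    if (!changed) break
  }
  bg <- rep(NA_real_, window)
  for (d in seq_len(min(window, n - 1))) {
    vals <- c()
    for (i in seq_len(n - d)) {
      if (valid[i] && valid[i + d]) vals <- c(vals, cm[i, i + d])
    }
    if (length(vals)) bg[d] <- mean(vals)
  }
  corr <- weight <- matrix(NA_real_, n, n)
  for (A in seq_len(n - 1)) {
    for (B in (A + 1):min(n, A + window)) {
      if (!valid[A] || !valid[B] || is.na(bg[B - A]) || bg[B - A] <= 0) next
      xs <- ys <- c()
      for (j in seq_len(n)) {
        if (j %in% c(A, B) || !valid[j]) next
        da <- abs(j - A); db <- abs(j - B)
        if (da > window || db > window) next
        if (is.na(bg[da]) || is.na(bg[db]) || bg[da] <= 0 || bg[db] <= 0) next
        if (cm[A, j] <= 0 || cm[B, j] <= 0) next
        xs <- c(xs, log(cm[A, j] / bg[da]))
        ys <- c(ys, log(cm[B, j] / bg[db]))
      }
      if (length(xs) >= 3 && stats::sd(xs) > 1e-8 && stats::sd(ys) > 1e-8) {
        corr[A, B] <- stats::cor(xs, ys)
        weight[A, B] <- sqrt(cm[A, B] / bg[B - A] + 1)
      }
    }
  }
  list(valid = valid, bg = bg, corr = corr, weight = weight)
}

test_that("band filtering removes dead bins and is idempotent", {
  m <- small_replicate(n_bins = 40, n = 2e4)
  f <- filter_bins(m, window = 8)
  expect_true(all(f$valid_mask)) # dense synthetic band: nothing removed

  cm <- m$counts
  cm[7, ] <- 0; cm[, 7] <- 0
  m7 <- contact_matrix(cm, 40000)
  f7 <- filter_bins(m7, window = 8)
  expect_false(f7$valid_mask[7])
  expect_equal(sum(!f7$valid_mask), 1)
  again <- filter_bins(f7$matrix, window = 8)
  expect_true(all(again$valid_mask))
})

test_that("the distance background averages retained pairs per distance", {
  const <- contact_matrix(matrix(5, 12, 12), 40000)
  bg <- distance_background(const, window = 8)
  expect_true(all(bg == 5))

  toy <- contact_matrix(matrix(c(0, 4, 0, 4, 0, 2, 0, 2, 0), 3), 40000)
  expect_equal(distance_background(toy, window = 2)[1], 3) # mean of {4, 2}

  # a distance with no retained pair is NA, not 0
  mask <- rep(TRUE, 12); mask[7:12] <- FALSE
  bg2 <- distance_background(const, valid_mask = mask, window = 8)
  expect_true(all(is.na(bg2[6:8])))
  expect_true(all(bg2[1:5] == 5))
})

test_that("transform entries match the brute-force oracle exactly", {
  for (seed in c(13, 14)) {
    gt <- simulate_cell_type(20, seed = seed)
    m <- sample_replicate(gt, 4e3, seed = seed + 1)
    qt <- quasar_transform(m, window = 8)
    bf <- brute_quasar(m$counts, 8)
    expect_equal(qt$valid_mask, bf$valid)
    expect_equal(qt$background, bf$bg)
    expect_equal(qt$corr, bf$corr, tolerance = 1e-10)
    expect_equal(qt$weights, bf$weight, tolerance = 1e-10)
    ok <- !is.na(qt$weights)
    expect_true(all(qt$weights[ok] >= 1))
    expect_true(all(abs(qt$corr[!is.na(qt$corr)]) <= 1))
  }
})

test_that("a matrix equal to its background has no defined correlations", {
  # flat matrix: enrichment 1 everywhere, log-enrichment 0, zero variance
  flat <- contact_matrix(matrix(6, 30, 30), 40000)
  qt <- quasar_transform(flat, window = 8)
  expect_true(all(is.na(qt$corr)))
  expect_warning(res <- quasar_qc(flat, window = 8), "undefined")
  expect_true(is.na(res))
})

test_that("the replicate score is 1 at identity and symmetric", {
  a <- small_replicate(n_bins = 60, n = 6e4, seed = 41)
  b <- small_replicate(n_bins = 60, n = 6e4, seed = 43)
  expect_equal(quasar_rep(a, a, window = 20), 1, tolerance = 1e-12)
  s <- quasar_rep(a, b, window = 20)
  expect_equal(quasar_rep(b, a, window = 20), s, tolerance = 1e-12)
  expect_true(abs(s) <= 1)
})

test_that("the quality score separates structure from random ligation", {
  # no distance-conditional structure beyond the background: QC near 0
  gt <- simulate_cell_type(200, seed = 51)
  base <- sample_replicate(gt, 1e6, seed = 52)
  qcs <- vapply(1:20, function(i) {
    quasar_qc(random_ligation_noise(base, seed = 100 + i))
  }, 0)
  expect_lt(abs(mean(qcs)), 0.01)

  # strongly TAD-structured matrix: enriched cells coincide with
  # correlated rows, QC > 0
  gt2 <- simulate_cell_type(200, n_tads = 10, tad_enrichment = 5, seed = 53)
  m2 <- sample_replicate(gt2, 1e6, seed = 54)
  expect_gt(quasar_qc(m2), 0.005)

  # pooled vs per-chromosome averaging agree for identical chromosomes
  qc1 <- quasar_qc(list(m2, m2), pooled = TRUE)
  qc2 <- quasar_qc(list(m2, m2), pooled = FALSE)
  expect_equal(qc1, qc2, tolerance = 1e-12)
  expect_equal(qc1, quasar_qc(m2), tolerance = 1e-12)
})
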