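test_that("genome scores average defined chromosomes and warn on gaps", {
  expect_equal(genome_score(c(chr1 = 0.8, chr2 = 0.9)), 0.85)
  expect_equal(genome_score(c(chr1 = 0.42)), 0.42)
  expect_warning(s <- genome_score(c(chr1 = NA, chr2 = 0.7)), "excluded")
  expect_equal(s, 0.7)
  expect_warning(res <- genome_score(c(chr1 = NA_real_)), "undefined")
  expect_true(is.na(res))
  expect_error(genome_score(numeric()), "at least one")
})

test_that("empirical thresholds implement the midpoint rule", {
  th <- empirical_threshold(c(0.1, 0.6), c(0.8, 0.95))
  expect_equal(th$threshold, 0.7)
  expect_equal(th$margin, 0.2)
  th2 <- empirical_threshold(c(0.9), c(0.7))
  expect_equal(th2$threshold, 0.8)
  expect_lt(th2$margin, 0)
  th3 <- empirical_threshold(0.5, 0.5)
  expect_equal(th3$threshold, 0.5)
  expect_equal(th3$margin, 0)
  expect_error(empirical_threshold(numeric(), 0.5), "non-empty")
})

test_that("ranking evaluation separates replicate classes on a small benchmark", {
  bench <- make_benchmark(n_cell_types = 2, reps_per_type = 2,
                          n_interactions = 3e5, n_bins = 120, seed = 10)
  ev <- ranking_evaluation(bench, "hicrep", h = 3, max_distance_bins = 60,
                           seed = 2)
  expect_equal(nrow(ev$scores), nrow(bench$pairs))
  expect_equal(ev$ordering_accuracy, 1)
  expect_true(all(ev$type_ordering))
  expect_gt(ev$threshold$margin, 0)
  # perfect separation: KS statistic 1 (2 vs 4 samples cannot reach p < 0.05)
  expect_equal(ev$ks$statistic, 1)
  expect_lt(ev$ks$p.value, 0.1)
})

test_that("noise response curves are deterministic and structured", {
  m <- small_replicate(n_bins = 80, n = 1e5)
  nr <- noise_response_curve(m, "genomedisco", levels = c(0, 0.25, 0.5),
                             seed = 31)
  expect_equal(nr$level, c(0, 0.25, 0.5))
  expect_gt(nr$score[1], 0.9) # resampling loss only at level 0
  expect_true(all(diff(nr$score) < 0))
  nr2 <- noise_response_curve(m, "genomedisco", levels = c(0, 0.25, 0.5),
                              seed = 31)
  expect_identical(nr, nr2)
})

test_that("the CLI scores, simulates and round-trips files", {
  dir <- withr::local_tempdir()
  a <- small_replicate(n_bins = 50, n = 4e4, seed = 61)
  b <- small_replicate(n_bins = 50, n = 4e4, seed = 63)
  fa <- file.path(dir, "a.tsv"); fb <- file.path(dir, "b.tsv")
  write_contact_matrix(a, fa)
  write_contact_matrix(b, fb)

  out <- capture.output(
    status <- hic3dqc_main(c("score", "--method", "hicrep", "--a", fa,
                             "--b", fb, "--resolution", "40000", "--h", "2")))
  expect_equal(status, 0L)
  got <- as.numeric(strsplit(out, "\t")[[1]][2])
  expect_equal(got, scc(a, b, h = 2), tolerance = 1e-5)

  out <- capture.output(
    status <- hic3dqc_main(c("qc", "--resolution", "40000", "--window", "20",
                             fa, fb)))
  expect_equal(status, 0L)
  expect_match(out, "^quasar-qc\t")

  synth_dir <- file.path(dir, "synth")
  status <- hic3dqc_main(c("synth", "--n-bins", "40", "--n-interactions",
                           "20000", "--out", synth_dir, "--seed", "3"))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(synth_dir, "manifest.json")))
  expect_true(file.exists(file.path(synth_dir, "type1_rep1.tsv")))
  back <- read_contact_matrix(file.path(synth_dir, "type1_rep1.tsv"),
                              "triplet", 40000)
  expect_equal(back$n_bins, 40)

  fd <- file.path(dir, "down.tsv")
  status <- hic3dqc_main(c("downsample", "--matrix", fa, "--resolution",
                           "40000", "--n", "1000", "--out", fd, "--seed", "5"))
  expect_equal(status, 0L)
  expect_equal(total_interactions(read_contact_matrix(fd, "triplet", 40000)),
               1000)

  expect_equal(hic3dqc_main(c("bogus")), 2L)
  expect_equal(hic3dqc_main(c("score", "--method", "hicrep")), 1L)
})
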