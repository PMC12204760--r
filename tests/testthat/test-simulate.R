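desk <- function(beta, seed = 1L, n = 1000L, molecules = 2e4,
                 depth = 2e5, ...) {
  sim_config(n_transcripts = n, total_molecules = molecules,
             target_beta = beta, depth = depth, seed = seed, ...)
}

test_that("simulate_whole_cell conserves molecules and is reproducible", {
  cfg <- desk(0.7, seed = 21)
  tx <- simulate_whole_cell(cfg)
  expect_equal(sum(tx$m_w), cfg$total_molecules)
  expect_true(all(tx$length >= 200))
  # degenerate single transcript holds everything
  one <- simulate_whole_cell(desk(0.7, n = 1))
  expect_equal(one$m_w, one$config$total_molecules)
  # fixed seed -> bit-identical
  expect_identical(simulate_whole_cell(cfg), tx)
  expect_error(sim_config(zipf_exponent = 0), "zipf_exponent")
})

test_that("split_fractions conserves m_w = m_n + m_c and hits target beta", {
  for (target in c(0.3, 0.5, 0.7, 0.9)) {
    tx <- split_fractions(simulate_whole_cell(desk(target, seed = 4)))
    expect_equal(tx$m_n + tx$m_c, tx$m_w)
    expect_true(all(tx$m_n >= 0 & tx$m_c >= 0))
    realized <- sum(tx$m_c * tx$length) / sum(tx$m_w * tx$length)
    expect_equal(realized, target, tolerance = 0.002 / target)
    expect_equal(tx$true_beta, realized)
  }
})

test_that("nb-difference split also conserves molecules and calibrates", {
  cfg <- desk(0.65, seed = 9, split_strategy = "nb-difference")
  tx <- split_fractions(simulate_whole_cell(cfg))
  expect_equal(tx$m_n + tx$m_c, tx$m_w)
  expect_lte(abs(tx$true_beta - 0.65), 0.002)
})

test_that("unreachable targets error with the achievable range", {
  # one transcript with a tiny NB gap cannot push beta near 1
  cfg <- sim_config(n_transcripts = 5, total_molecules = 1000,
                    target_beta = 0.99, nb_mean = 0.01,
                    split_strategy = "nb-difference", seed = 2)
  expect_error(split_fractions(simulate_whole_cell(cfg)), "unreachable")
})

test_that("balanced split with equal lengths gives mean true LI near 0.5", {
  lis <- vapply(1:20, function(s) {
    cfg <- sim_config(n_transcripts = 400, total_molecules = 2e4,
                      target_beta = 0.5, length_sdlog = 0, seed = 1000 + s)
    tx <- split_fractions(simulate_whole_cell(cfg))
    mean(tx$true_li, na.rm = TRUE)
  }, 0)
  expect_equal(mean(lis), 0.5, tolerance = 0.02)
})

test_that("simulate_reads conserves depth and matches Eq-3 expectations", {
  tx <- split_fractions(simulate_whole_cell(desk(0.7, seed = 5)))
  r <- simulate_reads(tx, "cytosolic", depth = 2e5, seed = 6)
  expect_equal(sum(r$reads), 2e5)

  # two transcripts with m*l weights 1:3 -> reads split 1:3 on average
  toy <- structure(list(transcript_id = c("a", "b"), length = c(1, 3),
                        m_w = c(1, 1), m_n = NULL, m_c = NULL,
                        config = desk(0.5)),
                   class = "SimulatedTranscriptome")
  mc <- rowMeans(vapply(1:30, function(s) {
    simulate_reads(toy, "whole_cell", depth = 4e4, seed = s)$reads
  }, numeric(2)))
  expect_equal(mc, expected_reads(c(1, 1), c(1, 3), 4e4),
               tolerance = 0.02)

  # single-transcript fraction receives the full depth
  one <- structure(list(transcript_id = "a", length = 100, m_w = 5,
                        config = desk(0.5)),
                   class = "SimulatedTranscriptome")
  expect_equal(simulate_reads(one, "whole_cell", depth = 123,
                              seed = 1)$reads, 123)
  expect_error(simulate_reads(tx, "nuclear", depth = 0), "depth")
})

test_that("fpkm_from_reads applies the definition", {
  expect_equal(fpkm_from_reads(100, 1000, depth = 1e6), 100)
  expect_equal(fpkm_from_reads(0, 500, depth = 10), 0)
  r <- list(reads = c(10, 20), depth = 1e6, fraction = "nuclear")
  expect_equal(fpkm_from_reads(r, c(1000, 2000)), c(10, 10))
})

test_that("noise-free pipeline: LI with true beta equals m_c/m_w exactly", {
  tx <- split_fractions(simulate_whole_cell(desk(0.75, seed = 13)))
  lens <- tx$length
  fn <- fpkm_from_reads(expected_reads(tx$m_n, lens, 1e6), lens, 1e6)
  fc <- fpkm_from_reads(expected_reads(tx$m_c, lens, 1e6), lens, 1e6)
  li <- suppressMessages(localization_index(fn, fc, tx$true_beta))
  truth <- tx$true_li
  ok <- !is.na(truth) & !is.na(li)
  expect_equal(li[ok], truth[ok], tolerance = 1e-12)
})

test_that("simulate_fraction_dataset is deterministic and writes TSVs", {
  cfg <- desk(0.6, seed = 31, n = 300, molecules = 5000, depth = 5e4)
  out1 <- file.path(tempdir(), "sim_a"); out2 <- file.path(tempdir(), "sim_b")
  s1 <- suppressMessages(simulate_fraction_dataset(cfg, out = out1))
  s2 <- suppressMessages(simulate_fraction_dataset(cfg, out = out2))
  expect_identical(s1$truth, s2$truth)
  for (f in c("whole_cell.tsv", "nuclear.tsv", "cytosolic.tsv",
              "ground_truth.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # reads sum to depth in every fraction
  counts <- fraction_matrix(s1$fqs, "expected_count")
  expect_equal(unname(colSums(counts)), rep(5e4, 3))
  # conservation propagates to the truth table
  expect_equal(s1$truth$m_n + s1$truth$m_c, s1$truth$m_w)
})

test_that("naive LI error grows with |beta - 0.5| (10+ seeds)", {
  med_abs_err <- function(beta) {
    vapply(1:10, function(s) {
      cfg <- desk(beta, seed = 500 + s)
      sim <- suppressMessages(simulate_fraction_dataset(cfg))
      fpkm <- fraction_matrix(sim$fqs, "fpkm")
      naive <- suppressMessages(naive_li(fpkm[, "nuclear"],
                                         fpkm[, "cytosolic"]))
      truth <- sim$truth$true_li
      ok <- !is.na(naive) & !is.na(truth) & sim$truth$m_w > 0
      median(abs(naive[ok] - truth[ok]))
    }, 0)
  }
  expect_gt(median(med_abs_err(0.8)), median(med_abs_err(0.5)))
})
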