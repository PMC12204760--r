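test_that("two-gene worked example reproduces the published indices", {
  # cell type 2: beta = 0.8; depth-1000 expected reads per fraction
  fqs2 <- fig1_fraction_set(2)
  fpkm <- fraction_matrix(fqs2, "fpkm")
  expect_equal(fig1_beta(2), 0.8)
  expect_equal(fig1_beta(1), 0.5)

  naive <- naive_li(fpkm[, "nuclear"], fpkm[, "cytosolic"])
  expect_equal(round(naive[["A"]], 2), 0.27)
  expect_equal(round(naive[["B"]], 2), 0.69)

  li <- localization_index(fpkm[, "nuclear"], fpkm[, "cytosolic"],
                           beta = 0.8)
  expect_equal(li[["A"]], 0.6, tolerance = 1e-12)
  expect_equal(li[["B"]], 0.9, tolerance = 1e-12)

  # cell type 1: beta = 0.5, naive equals the true cytosolic proportion
  fqs1 <- fig1_fraction_set(1)
  fpkm1 <- fraction_matrix(fqs1, "fpkm")
  naive1 <- naive_li(fpkm1[, "nuclear"], fpkm1[, "cytosolic"])
  expect_equal(round(naive1[["B"]], 2), 0.45)
  expect_equal(naive1[["A"]], 0.6, tolerance = 1e-12)

  # li_table wires the same numbers
  tab <- li_table(fqs2, beta = 0.8)
  expect_equal(tab$li, c(0.6, 0.9), tolerance = 1e-12)
  expect_equal(attr(tab, "beta_used"), 0.8)
})

test_that("localization_index boundaries, NA propagation and beta = 0.5", {
  expect_equal(localization_index(0, 3, 0.7), 1)
  expect_equal(localization_index(3, 0, 0.7), 0)
  expect_equal(naive_li(2, 2), 0.5)
  expect_true(is.na(suppressMessages(localization_index(0, 0, 0.7))))
  # LI at beta 0.5 is the naive LI for any inputs
  set.seed(5)
  n <- rexp(50); c_ <- rexp(50)
  expect_equal(localization_index(n, c_, 0.5), naive_li(n, c_))
  expect_error(localization_index(-1, 1, 0.5), "non-negative")
  expect_error(localization_index(1, 1, 1), "beta < 1")
})

test_that("LI is strictly increasing in beta; naive underestimates for beta > 0.5", {
  set.seed(6)
  n <- rexp(20, 1 / 3) + 0.1
  c_ <- rexp(20, 1 / 3) + 0.1
  betas <- seq(0.05, 0.95, by = 0.05)
  li_mat <- sapply(betas, function(b) localization_index(n, c_, b))
  expect_true(all(diff(t(li_mat)) > 0))
  expect_true(all(naive_li(n, c_) < localization_index(n, c_, 0.8)))
  expect_true(all(naive_li(n, c_) > localization_index(n, c_, 0.3)))
})

test_that("averaging across replicates precedes classification", {
  t1 <- make_li_table(c("A", "B", "C"), c(0.4, 0.2, NA))
  t2 <- make_li_table(c("A", "B", "C"), c(0.6, 0.2, 0.9))
  t3 <- make_li_table(c("A", "B", "C"), c(0.5, 0.8, NA))
  avg <- average_li_across_replicates(list(t1, t2, t3))
  expect_equal(avg$li, c(0.5, 0.4, 0.9))  # NA excluded from the mean
  expect_identical(average_li_across_replicates(list(t1)), t1)
  expect_error(
    average_li_across_replicates(list(t1, make_li_table("A", 0.5))),
    "transcript index")
})

test_that("classification schemes apply their thresholds", {
  tab <- make_li_table(paste0("T", 1:5), c(0.5, 0.39, 0.61, 0.95, NA))
  t46 <- classify_localization(tab, "threshold_04_06")
  expect_equal(t46$class_label,
               c("unassigned", "nuclear", "cytosolic", "cytosolic",
                 "unassigned"))
  half <- classify_localization(tab, "halfline")
  expect_equal(half$class_label,
               c("cytosolic", "nuclear", "cytosolic", "cytosolic",
                 "unassigned"))
  expect_error(classify_localization(tab, "nope"), "unknown")
})

test_that("consistency_by_breadth counts always-localized transcripts", {
  tabs <- list(
    s1 = make_li_table(c("cyt", "mix", "nuc", "half"),
                       c(0.6, 0.6, 0.3, 0.5)),
    s2 = make_li_table(c("cyt", "mix", "nuc", "half"),
                       c(0.7, 0.4, 0.2, 0.5)),
    s3 = make_li_table(c("cyt", "nuc"), c(0.9, 0.1))
  )
  out <- suppressMessages(consistency_by_breadth(tabs))
  b3 <- out[out$n_samples_expressed == 3, ]
  expect_equal(b3$n_transcripts, 2)        # cyt, nuc
  expect_equal(b3$n_always_cytosolic, 1)   # cyt
  expect_equal(b3$n_always_nuclear, 1)     # nuc
  b2 <- out[out$n_samples_expressed == 2, ]
  # "mix" is neither; "half" at exactly 0.5 counts in both (inclusive)
  expect_equal(b2$n_always_cytosolic, 1)
  expect_equal(b2$n_always_nuclear, 1)
})

test_that("strong_localization_sets enforces breadth and strict cutoffs", {
  mk <- function(li) make_li_table(paste0("T", seq_along(li)), li)
  tabs <- lapply(1:5, function(s) {
    make_li_table(c("strong_cyt", "one_fail", "strong_nuc", "narrow"),
                  c(c(0.95, 0.92, 0.91, 0.99, 0.93)[s],
                    c(0.95, 0.95, 0.95, 0.95, 0.89)[s],
                    c(0.1, 0.2, 0.25, 0.05, 0.29)[s],
                    if (s <= 4) 0.99 else NA))
  })
  sets <- strong_localization_sets(tabs, min_samples = 5)
  expect_identical(sets$cytosolic, "strong_cyt")
  expect_identical(sets$nuclear, "strong_nuc")
})

test_that("li_error is the signed deviation from simulated truth", {
  tab <- make_li_table(c("A", "B"), c(0.7, 0.5))
  err <- li_error(tab, c(A = 0.6, B = 0.5))
  expect_equal(as.numeric(err), c(0.1, 0))
  expect_equal(attr(err, "summary")[["median"]], 0.05)
  expect_error(li_error(tab, c(A = 0.6)), "missing truth")
})
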