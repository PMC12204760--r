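toy_meta <- function() {
  data.frame(
    transcript_id = c("T1", "T2"),
    gene_id = c("G1", "G2"),
    biotype = c("protein_coding", "lncRNA"),
    chromosome = c("chr1", "chr1"),
    strand = c("+", "+"),
    stringsAsFactors = FALSE
  ) -> m
  m$exons <- list(cbind(start = c(100L, 301L), end = c(200L, 400L)),
                  cbind(start = 50L, end = 149L))
  m$cds <- list(cbind(start = 150L, end = 350L), NULL)
  m
}

test_that("compute_transcript_features: lengths, introns, UTRs, GC", {
  feats <- compute_transcript_features(toy_meta())
  t1 <- feats[feats$transcript_id == "T1", ]
  expect_equal(t1$total_exon_length, 201)   # (200-100+1) + (400-301+1)
  expect_equal(t1$total_intron_length, 100) # span 301 - exons 201
  expect_equal(t1$n_introns, 1)
  expect_equal(t1$utr5_length, 50)          # exon bases before CDS start
  expect_equal(t1$utr3_length, 50)          # exon bases after CDS end
  t2 <- feats[feats$transcript_id == "T2", ]
  expect_equal(t2$total_intron_length, 0)
  expect_equal(t2$n_introns, 0)
  expect_true(is.na(t2$utr5_length))

  # GC over the spliced sequence
  meta <- toy_meta()[2, , drop = FALSE]
  meta$exons <- list(cbind(start = c(1L, 5L), end = c(4L, 8L)))
  meta$cds <- list(NULL)
  seqs <- c(chr1 = "GGCCATAT")
  expect_equal(compute_transcript_features(meta, seqs)$gc_content, 0.5)
  meta$exons <- list(cbind(start = 5L, end = 9L))
  expect_error(compute_transcript_features(meta, seqs), "bounds")
})

test_that("compare_features_by_class runs Wilcoxon per feature", {
  set.seed(14)
  n <- 30
  feats <- data.frame(
    transcript_id = paste0("T", 1:(2 * n)),
    gc_content = c(rnorm(n, 0.6, 0.02), rnorm(n, 0.4, 0.02)),
    total_exon_length = rep(1000, 2 * n)
  )
  classes <- setNames(rep(c("nuclear", "cytosolic"), each = n),
                      feats$transcript_id)
  out <- compare_features_by_class(feats, classes)
  gc <- out[out$feature == "gc_content", ]
  # nuclear GC constructed higher -> cytosolic - nuclear < 0, significant
  expect_lt(gc$median_diff, 0)
  expect_lt(gc$p_value, 1e-6)
  # identical distributions -> p ~ 1, zero median difference
  ex <- out[out$feature == "total_exon_length", ]
  expect_equal(ex$median_diff, 0)
  expect_gt(ex$p_value, 0.9)
  expect_error(
    compare_features_by_class(feats, setNames(rep("nuclear", 2 * n),
                                              feats$transcript_id)),
    "at least 2")
})

test_that("localization_specific_sets reads 'only' strictly", {
  classes <- c(n1 = "nuclear", n2 = "nuclear", c1 = "cytosolic",
               u1 = "unassigned")
  fmap <- list(int_nuc = c("n1", "n2"),
               int_mixed = c("n1", "c1"),
               ex_cyt = "c1",
               ex_unassigned = c("c1", "u1"))
  sets <- localization_specific_sets(fmap, classes)
  expect_identical(sets$nuclear, "int_nuc")
  expect_identical(sets$cytosolic, "ex_cyt")
})

test_that("enrichment_test: ratio, exact tail, Bonferroni", {
  r <- enrichment_test(8, 20, 100, 1000)
  expect_equal(r$enrichment_ratio, 4)
  # null ratio
  expect_equal(enrichment_test(10, 100, 100, 1000)$enrichment_ratio, 1)

  # brute-force enumeration oracle for every N <= 12 case tried
  set.seed(15)
  for (i in 1:20) {
    N <- sample(5:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(enrichment_test(k, n, K, N)$p_value,
                 hyper_tail_enum(k, K, N, n), tolerance = 1e-12)
  }

  # scale invariance of the ratio
  r1 <- enrichment_test(3, 10, 30, 100)$enrichment_ratio
  r2 <- enrichment_test(9, 30, 90, 300)$enrichment_ratio
  expect_equal(r1, r2)

  # Bonferroni never decreases p and caps at 1
  p <- enrichment_test(3, 5, 4, 10, n_tests = 8)
  expect_gte(p$p_adjusted, p$p_value)
  expect_lte(p$p_adjusted, 1)
  expect_error(enrichment_test(6, 5, 10, 20), "bounds")
})

test_that("splicing_enrichment applies strict score thresholds", {
  scores <- data.frame(
    feature_id = paste0("i", 1:10),
    score = c(0.9, 0.8, 0.5, 0.2, 0.1, 0.7, 0.3, 0.6, 0.4, 0.55))
  specific <- c("i1", "i2", "i3")  # two hits at > 0.5 (0.5 itself is not)
  r <- splicing_enrichment(scores, specific, direction = "high")
  expect_equal(r$k_hits_in_set, 2)
  expect_equal(r$n_set, 3)
  expect_equal(r$K_hits_total, 5)  # 0.9 0.8 0.7 0.6 0.55
  expect_equal(r$N_total, 10)
  low <- splicing_enrichment(scores, c("i4", "i5"), direction = "low")
  expect_equal(low$k_hits_in_set, 2)
  expect_equal(low$K_hits_total, 4) # 0.2 0.1 0.3 0.4
})
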