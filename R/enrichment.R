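# Downstream statistics: transcript structural/sequence features compared
# between nuclear and cytosolic transcripts, and over-representation of
# poorly spliced features (high intron-retention, low exon inclusion) in
# localization-specific feature sets.

#' Structural and sequence features per transcript
#'
#' From exon intervals (1-based inclusive): total exon length, total
#' intron length (transcript span minus exon length), intron count,
#' optional 5'/3' UTR lengths from CDS bounds, and GC content over the
#' spliced sequence when chromosome sequences are supplied.
#'
#' @param meta Transcript metadata from [read_gtf_metadata()].
#' @param sequences Optional named character vector (or
#'   `Biostrings::DNAStringSet`) of chromosome sequences for GC content.
#' @return A data.frame with `transcript_id`, `total_exon_length`,
#'   `total_intron_length`, `n_introns`, `utr5_length`, `utr3_length`
#'   (`NA` without CDS) and `gc_content` (`NA` without sequences).
#' @export
compute_transcript_features <- function(meta, sequences = NULL) {
  if (!is.null(sequences)) {
    nm <- names(sequences)
    sequences <- as.character(sequences)  # drops names; restore them
    names(sequences) <- nm
  }
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    exons <- meta$exons[[i]]
    if (any(exons[, "start"] > exons[, "end"])) {
      stop("exon with start > end for ", meta$transcript_id[i])
    }
    widths <- exons[, "end"] - exons[, "start"] + 1
    exon_len <- sum(widths)
    span <- max(exons[, "end"]) - min(exons[, "start"]) + 1
    n_ex <- nrow(exons)
    utr5 <- NA_real_; utr3 <- NA_real_
    cds <- meta$cds[[i]]
    if (!is.null(cds) && nrow(cds) > 0) {
      cds_lo <- min(cds[, "start"]); cds_hi <- max(cds[, "end"])
      left <- sum(pmax(0, pmin(exons[, "end"], cds_lo - 1) -
                         exons[, "start"] + 1))
      right <- sum(pmax(0, exons[, "end"] -
                          pmax(exons[, "start"], cds_hi + 1) + 1))
      if (meta$strand[i] == "-") {
        utr5 <- right; utr3 <- left
      } else {
        utr5 <- left; utr3 <- right
      }
    }
    gc <- NA_real_
    if (!is.null(sequences)) {
      chrom <- meta$chromosome[i]
      if (!chrom %in% names(sequences)) {
        stop("no sequence for chromosome ", chrom)
      }
      seq <- sequences[[chrom]]
      if (max(exons[, "end"]) > nchar(seq)) {
        stop("exon beyond chromosome bounds for ", meta$transcript_id[i])
      }
      spliced <- paste(substring(seq, exons[, "start"], exons[, "end"]),
                       collapse = "")
      bases <- strsplit(toupper(spliced), "")[[1]]
      gc <- mean(bases %in% c("G", "C"))
    }
    data.frame(transcript_id = meta$transcript_id[i],
               total_exon_length = exon_len,
               total_intron_length = span - exon_len,
               n_introns = n_ex - 1L,
               utr5_length = utr5, utr3_length = utr3,
               gc_content = gc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare transcript features between nuclear and cytosolic classes
#'
#' Two-sided Wilcoxon rank-sum test plus median difference
#' (cytosolic - nuclear) for every numeric feature column.
#'
#' @param features Feature table from [compute_transcript_features()].
#' @param classes Named character vector (`"nuclear"` / `"cytosolic"`) or
#'   a `LocalizationTable` with `class_label` set.
#' @return A data.frame with `feature`, `median_nuclear`,
#'   `median_cytosolic`, `median_diff`, `p_value`.
#' @export
compare_features_by_class <- function(features, classes) {
  if (inherits(classes, "LocalizationTable") || is.data.frame(classes)) {
    classes <- setNames(classes$class_label, classes$transcript_id)
  }
  cls <- classes[features$transcript_id]
  keep <- cls %in% c("nuclear", "cytosolic")
  features <- features[keep, , drop = FALSE]
  cls <- cls[keep]
  if (sum(cls == "nuclear") < 2 || sum(cls == "cytosolic") < 2) {
    stop("need at least 2 transcripts per class")
  }
  feat_cols <- setdiff(names(features), "transcript_id")
  rows <- lapply(feat_cols, function(f) {
    x <- features[[f]]
    nuc <- x[cls == "nuclear" & !is.na(x)]
    cyt <- x[cls == "cytosolic" & !is.na(x)]
    if (length(nuc) < 2 || length(cyt) < 2) {
      return(data.frame(feature = f, median_nuclear = NA_real_,
                        median_cytosolic = NA_real_,
                        median_diff = NA_real_, p_value = NA_real_))
    }
    p <- suppressWarnings(
      stats::wilcox.test(cyt, nuc, alternative = "two.sided")$p.value)
    # fully tied data puts the statistic at its null expectation with zero
    # variance; report the null p-value rather than NaN
    if (is.nan(p)) p <- 1
    data.frame(feature = f,
               median_nuclear = stats::median(nuc),
               median_cytosolic = stats::median(cyt),
               median_diff = stats::median(cyt) - stats::median(nuc),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Localization-specific exon / intron sets
#'
#' A feature (exon or intron) is nuclear-specific when every transcript
#' hosting it is classified nuclear, and cytosolic-specific when every
#' host is cytosolic. "Only" is read strictly: a single mixed or
#' unassigned host disqualifies the feature.
#'
#' @param feature_map Named list (or data.frame with columns `feature_id`,
#'   `transcript_id`) mapping each feature to its host transcripts.
#' @param classes Named character vector of class labels per transcript,
#'   or a classified `LocalizationTable`.
#' @return List with character vectors `nuclear` and `cytosolic`.
#' @export
localization_specific_sets <- function(feature_map, classes) {
  if (inherits(classes, "LocalizationTable") || is.data.frame(classes)) {
    classes <- setNames(classes$class_label, classes$transcript_id)
  }
  if (is.data.frame(feature_map)) {
    feature_map <- split(feature_map$transcript_id, feature_map$feature_id)
  }
  host_class <- lapply(feature_map, function(tx) {
    cl <- classes[tx]
    cl[is.na(cl)] <- "unassigned"
    cl
  })
  nuc <- names(feature_map)[vapply(host_class,
                                   function(cl) all(cl == "nuclear"),
                                   logical(1))]
  cyt <- names(feature_map)[vapply(host_class,
                                   function(cl) all(cl == "cytosolic"),
                                   logical(1))]
  list(nuclear = nuc, cytosolic = cyt)
}

#' Hypergeometric over-representation test with Bonferroni correction
#'
#' Enrichment ratio `(k/n) / (K/N)` and upper-tail hypergeometric
#' p-value `P(X >= k)` for `X ~ Hypergeom(N, K, n)`, Bonferroni-adjusted
#' over `n_tests` tests.
#'
#' @param hits_in_set Hits inside the feature set (k).
#' @param set_size Size of the feature set (n).
#' @param hits_total Hits in the whole universe (K).
#' @param universe Universe size (N).
#' @param n_tests Number of tests for the Bonferroni correction.
#' @param set_name Label carried into the result.
#' @return An `EnrichmentResult` data.frame row: `set_name`,
#'   `k_hits_in_set`, `n_set`, `K_hits_total`, `N_total`,
#'   `enrichment_ratio`, `p_value`, `p_adjusted`.
#' @export
enrichment_test <- function(hits_in_set, set_size, hits_total, universe,
                            n_tests = 1L, set_name = "set") {
  if (hits_in_set < 0 || hits_in_set > min(set_size, hits_total) ||
      set_size > universe || hits_total > universe || set_size < 1) {
    stop("invalid hypergeometric bounds: k=", hits_in_set, " n=", set_size,
         " K=", hits_total, " N=", universe)
  }
  ratio <- if (hits_total == 0) NA_real_ else
    (hits_in_set / set_size) / (hits_total / universe)
  p <- stats::phyper(hits_in_set - 1, hits_total, universe - hits_total,
                     set_size, lower.tail = FALSE)
  out <- data.frame(set_name = set_name,
                    k_hits_in_set = hits_in_set, n_set = set_size,
                    K_hits_total = hits_total, N_total = universe,
                    enrichment_ratio = ratio,
                    p_value = p,
                    p_adjusted = min(1, p * n_tests),
                    stringsAsFactors = FALSE)
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Splicing-efficiency enrichment in localization-specific features
#'
#' Wires the threshold rules to [enrichment_test()]: given a per-feature
#' splicing score table, features scoring as poorly spliced (IR-ratio
#' strictly above `cutoff` for introns, PSI strictly below `cutoff` for
#' exons) are tested for over-representation inside a localization-specific
#' feature set relative to all scored features.
#'
#' @param scores Data.frame with columns `feature_id` and `score` (PSI or
#'   IR-ratio).
#' @param specific_ids Character vector of localization-specific feature
#'   ids (from [localization_specific_sets()]).
#' @param direction `"high"` (hit when score > cutoff; IR-ratio) or
#'   `"low"` (hit when score < cutoff; PSI).
#' @param cutoff Score threshold (default 0.5, strict).
#' @param n_tests Bonferroni denominator.
#' @param set_name Label for the result.
#' @return An `EnrichmentResult` row.
#' @export
splicing_enrichment <- function(scores, specific_ids,
                                direction = c("high", "low"),
                                cutoff = 0.5, n_tests = 1L,
                                set_name = "set") {
  direction <- match.arg(direction)
  hit <- if (direction == "high") scores$score > cutoff
         else scores$score < cutoff
  in_set <- scores$feature_id %in% specific_ids
  enrichment_test(hits_in_set = sum(hit & in_set),
                  set_size = sum(in_set),
                  hits_total = sum(hit),
                  universe = nrow(scores),
                  n_tests = n_tests, set_name = set_name)
}
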