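#' Expression filter on CPM
#'
#' Keeps transcript i when `cpm_whole(i) >= threshold` and at least one of
#' the two fractions (nuclear, cytosolic) also reaches the threshold.
#' Comparison is inclusive. Low-expression transcripts carry mostly
#' quantification noise and would otherwise dilute the regression.
#'
#' @param fqs A `FractionQuantSet` with CPM computed
#'   (see [normalize_fraction_set()]).
#' @param threshold CPM threshold (default 1).
#' @return The filtered `FractionQuantSet`. Retained/dropped counts are
#'   reported via `message()`.
#' @export
filter_by_cpm <- function(fqs, threshold = 1.0) {
  stopifnot(inherits(fqs, "FractionQuantSet"))
  cpm <- fraction_matrix(fqs, "cpm")
  if (anyNA(cpm)) {
    stop("CPM not computed for all fractions; run normalize_fraction_set() ",
         "or compute_cpm() first")
  }
  keep <- cpm[, "whole_cell"] >= threshold &
    (cpm[, "nuclear"] >= threshold | cpm[, "cytosolic"] >= threshold)
  message("filter_by_cpm: retained ", sum(keep), " of ", length(keep),
          " transcripts (dropped ", sum(!keep), ")")
  subset_fraction_set(fqs, keep)
}

MITO_CHROMS <- c("chrm", "chrmt", "mt", "m")

#' Remove mitochondrially encoded transcripts
#'
#' Mitochondrial RNA is not partitioned by the nuclear envelope and must
#' not influence the nucleo-cytosolic volume split. Chromosome names
#' matching chrM / chrMT / MT / M (case-insensitive) are treated as
#' mitochondrial.
#'
#' @param fqs A `FractionQuantSet`.
#' @param meta Transcript metadata from [read_gtf_metadata()], covering
#'   every transcript in `fqs`.
#' @return The filtered `FractionQuantSet`.
#' @export
filter_mitochondrial <- function(fqs, meta) {
  stopifnot(inherits(fqs, "FractionQuantSet"))
  idx <- match(fqs$transcript_id, meta$transcript_id)
  if (anyNA(idx)) {
    missing <- fqs$transcript_id[is.na(idx)]
    stop("transcripts lacking metadata: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)",
                                          length(missing) - 5) else "")
  }
  mito <- tolower(meta$chromosome[idx]) %in% MITO_CHROMS
  if (any(mito)) {
    message("filter_mitochondrial: removed ", sum(mito),
            " mitochondrial transcripts")
  }
  subset_fraction_set(fqs, !mito)
}

#' Restrict replicates to transcripts present in all of them
#'
#' A replicate-concordance surrogate for npIDR filtering: a transcript is
#' kept only if it survived the transcript-level filters in every replicate
#' of the sample. With a single replicate this is the identity.
#'
#' @param reps List of `FractionQuantSet` objects for one sample, already
#'   filtered per replicate.
#' @return The list with every replicate restricted to the common
#'   transcript set.
#' @export
filter_replicate_presence <- function(reps) {
  stopifnot(length(reps) >= 1)
  if (length(reps) == 1) return(reps)
  shared <- Reduce(intersect, lapply(reps, `[[`, "transcript_id"))
  lapply(reps, function(fqs) subset_fraction_set(fqs, shared))
}

#' Restrict a replicate to an externally supplied keep-list
#'
#' Hook for reproducibility scores computed outside the package (for
#' instance npIDR < 0.1 in all three fractions): the keep-list file has one
#' transcript id per line.
#'
#' @param fqs A `FractionQuantSet`.
#' @param keep Character vector of transcript ids, or a path to a plain
#'   text file with one id per line.
#' @return The filtered `FractionQuantSet`.
#' @export
filter_by_keep_list <- function(fqs, keep) {
  stopifnot(inherits(fqs, "FractionQuantSet"))
  if (length(keep) == 1 && file.exists(keep)) {
    keep <- readLines(keep)
    keep <- keep[nzchar(keep)]
  }
  subset_fraction_set(fqs, fqs$transcript_id %in% keep)
}

#' Whole-cell-in-range outlier filter (constrained-minimization baseline)
#'
#' Retains transcript i only when its whole-cell FPKM lies inside the
#' closed interval spanned by its nuclear and cytosolic FPKMs:
#' `min(n, c) <= w <= max(n, c)`. Under the exact mixture model the
#' whole-cell value can never fall outside that range, so violations flag
#' measurement outliers. Used by the constrained least-squares baseline;
#' the Bayesian estimator does not need it.
#'
#' @param fqs A `FractionQuantSet` with FPKM computed.
#' @return The filtered `FractionQuantSet`.
#' @export
dai_outlier_filter <- function(fqs) {
  stopifnot(inherits(fqs, "FractionQuantSet"))
  fpkm <- fraction_matrix(fqs, "fpkm")
  if (anyNA(fpkm)) stop("FPKM not computed; run normalize_fraction_set()")
  lo <- pmin(fpkm[, "nuclear"], fpkm[, "cytosolic"])
  hi <- pmax(fpkm[, "nuclear"], fpkm[, "cytosolic"])
  keep <- fpkm[, "whole_cell"] >= lo & fpkm[, "whole_cell"] <= hi
  message("dai_outlier_filter: retained ", sum(keep), " of ", length(keep),
          " transcripts")
  subset_fraction_set(fqs, keep)
}

#' Exclude replicates with implausibly high estimated beta
#'
#' Estimates above the cutoff (default 0.95) typically reflect failed
#' fractionation or an unstable fit rather than biology; such replicates
#' are dropped from downstream localization analyses. The inequality is
#' strict: beta equal to the cutoff is retained.
#'
#' @param estimates Named numeric vector of beta estimates, one per
#'   replicate/sample.
#' @param cutoff Exclusion cutoff (default 0.95).
#' @return Character vector of retained names.
#' @export
exclude_high_beta_samples <- function(estimates, cutoff = 0.95) {
  if (length(estimates) == 0) return(character(0))
  if (any(estimates < 0 | estimates > 1)) {
    stop("beta estimates must lie in [0, 1]")
  }
  if (is.null(names(estimates))) {
    names(estimates) <- paste0("sample", seq_along(estimates))
  }
  excluded <- names(estimates)[estimates > cutoff]
  if (length(excluded) > 0) {
    message("exclude_high_beta_samples: excluded ",
            paste(excluded, collapse = ", "))
  }
  setdiff(names(estimates), excluded)
}
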