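# Per-transcript localization index (LI): the estimated proportion of a
# transcript's molecules residing in the cytosol, computed from nuclear and
# cytosolic FPKM together with the sample-level cytosolic volume fraction
# beta. LI = 0 is fully nuclear, 1 fully cytosolic.

#' Localization index of one transcript
#'
#' `LI = beta * c / ((1 - beta) * n + beta * c)` where n and c are the
#' nuclear and cytosolic FPKMs. Vectorized over transcripts. When both
#' FPKMs are zero the index is undefined and `NA` is returned.
#'
#' @param fpkm_n,fpkm_c Non-negative nuclear / cytosolic FPKM.
#' @param beta Cytosolic volume fraction, in (0, 1).
#' @return LI in \[0, 1\] (or `NA` where undefined).
#' @export
localization_index <- function(fpkm_n, fpkm_c, beta) {
  stopifnot(length(beta) == 1, beta > 0, beta < 1)
  if (any(fpkm_n < 0 | fpkm_c < 0, na.rm = TRUE)) {
    stop("FPKM values must be non-negative")
  }
  num <- beta * fpkm_c
  den <- (1 - beta) * fpkm_n + num
  out <- num / den
  undef <- den == 0
  if (any(undef, na.rm = TRUE)) {
    message("localization_index: ", sum(undef, na.rm = TRUE),
            " transcript(s) with zero FPKM in both fractions -> NA")
    out[undef] <- NA_real_
  }
  out
}

#' Naive localization index
#'
#' `c / (n + c)`, the FPKM ratio used when no whole-cell library exists.
#' Equals the localization index only when beta = 0.5; it underestimates
#' the true LI when beta > 0.5 and overestimates it when beta < 0.5.
#'
#' @inheritParams localization_index
#' @return The ratio in \[0, 1\] (`NA` where both FPKMs are zero).
#' @export
naive_li <- function(fpkm_n, fpkm_c) {
  localization_index(fpkm_n, fpkm_c, beta = 0.5)
}

#' Localization table for one replicate
#'
#' @param fqs A `FractionQuantSet` with FPKM computed.
#' @param beta Estimated cytosolic volume fraction for this replicate.
#' @return A `LocalizationTable`: data.frame with `transcript_id`, `li`,
#'   `naive_li`, `class_label` (initially `"unassigned"`), and attribute
#'   `beta_used`.
#' @export
li_table <- function(fqs, beta) {
  stopifnot(inherits(fqs, "FractionQuantSet"))
  fpkm <- fraction_matrix(fqs, "fpkm")
  if (nrow(fpkm) > 0 && anyNA(fpkm)) {
    stop("FPKM not computed; run normalize_fraction_set()")
  }
  out <- data.frame(
    transcript_id = fqs$transcript_id,
    li = localization_index(fpkm[, "nuclear"], fpkm[, "cytosolic"], beta),
    naive_li = naive_li(fpkm[, "nuclear"], fpkm[, "cytosolic"]),
    class_label = rep("unassigned", length(fqs$transcript_id)),
    stringsAsFactors = FALSE
  )
  attr(out, "beta_used") <- beta
  class(out) <- c("LocalizationTable", "data.frame")
  out
}

#' Average localization index across replicates
#'
#' Arithmetic mean of LI (and naive LI) per transcript across replicate
#' tables sharing the same transcript index (run
#' [filter_replicate_presence()] first). Missing LI values are excluded
#' from the mean. Averaging precedes classification.
#'
#' @param tables List of `LocalizationTable` objects.
#' @return A `LocalizationTable` with averaged indices; attribute
#'   `beta_used` holds the per-replicate vector.
#' @export
average_li_across_replicates <- function(tables) {
  stopifnot(length(tables) >= 1)
  if (length(tables) == 1) return(tables[[1]])
  ids <- tables[[1]]$transcript_id
  for (t in tables[-1]) {
    if (!identical(t$transcript_id, ids)) {
      stop("replicate tables do not share a transcript index; ",
           "run filter_replicate_presence() first")
    }
  }
  li_mat <- vapply(tables, `[[`, numeric(length(ids)), "li")
  naive_mat <- vapply(tables, `[[`, numeric(length(ids)), "naive_li")
  if (is.null(dim(li_mat))) {
    li_mat <- matrix(li_mat, nrow = length(ids))
    naive_mat <- matrix(naive_mat, nrow = length(ids))
  }
  out <- data.frame(
    transcript_id = ids,
    li = rowMeans(li_mat, na.rm = TRUE),
    naive_li = rowMeans(naive_mat, na.rm = TRUE),
    class_label = rep("unassigned", length(ids)),
    stringsAsFactors = FALSE
  )
  out$li[is.nan(out$li)] <- NA_real_
  out$naive_li[is.nan(out$naive_li)] <- NA_real_
  attr(out, "beta_used") <- vapply(tables, attr, 0, "beta_used")
  class(out) <- c("LocalizationTable", "data.frame")
  out
}

#' Classify transcripts as nuclear / cytosolic
#'
#' Two schemes: `"threshold_04_06"` calls a transcript nuclear when
#' LI < 0.4 and cytosolic when LI > 0.6, leaving the middle band
#' unassigned; `"halfline"` splits at 0.5 (cytosolic when LI >= 0.5).
#' Transcripts with missing LI stay `"unassigned"`.
#'
#' @param table A `LocalizationTable`.
#' @param scheme `"threshold_04_06"` (default) or `"halfline"`.
#' @return The table with `class_label` filled in.
#' @export
classify_localization <- function(table, scheme = "threshold_04_06") {
  li <- table$li
  lab <- rep("unassigned", length(li))
  if (scheme == "threshold_04_06") {
    lab[!is.na(li) & li < 0.4] <- "nuclear"
    lab[!is.na(li) & li > 0.6] <- "cytosolic"
  } else if (scheme == "halfline") {
    lab[!is.na(li) & li >= 0.5] <- "cytosolic"
    lab[!is.na(li) & li < 0.5] <- "nuclear"
  } else {
    stop("unknown classification scheme: ", scheme)
  }
  table$class_label <- lab
  table
}

#' Cross-sample localization consistency by expression breadth
#'
#' For every transcript, counts the samples in which it is expressed
#' (i.e. present in that sample's table with a defined LI) and whether it
#' is cytosolic (LI >= 0.5) or nuclear (LI <= 0.5) in every one of them.
#' Transcripts sitting exactly at 0.5 everywhere satisfy both inclusive
#' criteria and are counted in both categories (logged). Results are
#' aggregated by breadth (number of samples expressed).
#'
#' @param tables Named list of `LocalizationTable` objects, one per sample.
#' @return A data.frame with one row per breadth: `n_samples_expressed`,
#'   `n_transcripts`, `n_always_cytosolic`, `n_always_nuclear`,
#'   `prop_always_cytosolic`, `prop_always_nuclear`.
#' @export
consistency_by_breadth <- function(tables) {
  stopifnot(length(tables) >= 2)
  per <- transcript_consistency(tables)
  both <- sum(per$always_cytosolic & per$always_nuclear)
  if (both > 0) {
    message("consistency_by_breadth: ", both,
            " transcript(s) at LI exactly 0.5 everywhere, counted in both ",
            "categories")
  }
  agg <- lapply(split(per, per$n_expressed), function(d) {
    data.frame(
      n_samples_expressed = d$n_expressed[1],
      n_transcripts = nrow(d),
      n_always_cytosolic = sum(d$always_cytosolic),
      n_always_nuclear = sum(d$always_nuclear),
      prop_always_cytosolic = mean(d$always_cytosolic),
      prop_always_nuclear = mean(d$always_nuclear)
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$n_samples_expressed), , drop = FALSE]
}

# Per-transcript expression breadth and all-sample localization flags.
transcript_consistency <- function(tables) {
  ids <- unique(unlist(lapply(tables, `[[`, "transcript_id")))
  li_mat <- matrix(NA_real_, length(ids), length(tables),
                   dimnames = list(ids, names(tables)))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    li_mat[match(t$transcript_id, ids), j] <- t$li
  }
  expressed <- !is.na(li_mat)
  n_expressed <- rowSums(expressed)
  always_cyt <- rowSums(li_mat >= 0.5 & expressed, na.rm = TRUE) == n_expressed
  always_nuc <- rowSums(li_mat <= 0.5 & expressed, na.rm = TRUE) == n_expressed
  data.frame(transcript_id = ids, n_expressed = n_expressed,
             always_cytosolic = always_cyt & n_expressed > 0,
             always_nuclear = always_nuc & n_expressed > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Strongly localized transcript sets
#'
#' Transcripts expressed in at least `min_samples` samples whose LI clears
#' a strict cutoff in every sample where they are expressed:
#' LI > `cyt_cut` everywhere for the strongly cytosolic set, LI <
#' `nuc_cut` everywhere for the strongly nuclear set.
#'
#' @param tables Named list of `LocalizationTable` objects.
#' @param min_samples Minimum expression breadth (default 5).
#' @param cyt_cut,nuc_cut Strict LI cutoffs (defaults 0.9 and 0.3).
#' @return List with character vectors `cytosolic` and `nuclear`.
#' @export
strong_localization_sets <- function(tables, min_samples = 5,
                                     cyt_cut = 0.9, nuc_cut = 0.3) {
  ids <- unique(unlist(lapply(tables, `[[`, "transcript_id")))
  li_mat <- matrix(NA_real_, length(ids), length(tables),
                   dimnames = list(ids, names(tables)))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    li_mat[match(t$transcript_id, ids), j] <- t$li
  }
  expressed <- !is.na(li_mat)
  n_expressed <- rowSums(expressed)
  broad <- n_expressed >= min_samples
  all_cyt <- rowSums(li_mat > cyt_cut & expressed, na.rm = TRUE) == n_expressed
  all_nuc <- rowSums(li_mat < nuc_cut & expressed, na.rm = TRUE) == n_expressed
  list(cytosolic = ids[broad & all_cyt], nuclear = ids[broad & all_nuc])
}

#' Localization-index error against simulation ground truth
#'
#' `error(i) = li(i) - truth(i)` where truth is the simulated cytosolic
#' molecule proportion `m_c(i) / m_w(i)`.
#'
#' @param table A `LocalizationTable`.
#' @param truth Named numeric vector (names = transcript ids) or a vector
#'   aligned with the table, of true cytosolic proportions.
#' @return Numeric vector of signed errors (one per transcript with
#'   defined LI), with a `summary` attribute (mean, median, IQR).
#' @export
li_error <- function(table, truth) {
  if (!is.null(names(truth))) {
    truth <- truth[table$transcript_id]
  } else if (length(truth) != nrow(table)) {
    stop("truth must be named or aligned with the table")
  }
  defined <- !is.na(table$li)
  if (anyNA(truth[defined])) {
    stop("missing truth for transcripts with defined LI")
  }
  err <- table$li[defined] - truth[defined]
  attr(err, "summary") <- c(mean = mean(err), median = stats::median(err),
                            iqr = unname(diff(stats::quantile(err,
                                                              c(0.25, 0.75)))))
  err
}

#' Write a localization table as TSV
#'
#' @param table A `LocalizationTable`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_li_table <- function(table, path) {
  out <- as.data.frame(table)
  out$beta_used <- paste(signif(attr(table, "beta_used"), 10),
                         collapse = ",")
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
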