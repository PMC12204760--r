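FRACTION_LABELS <- c("whole_cell", "nuclear", "cytosolic")

#' Read an RSEM-style isoform quantification table
#'
#' Parses a tab-separated quantification table of the kind produced by RSEM
#' (`isoforms.results`). Only the transcript id, effective length and
#' expected count columns are required; normalized units (CPM, FPKM) are
#' computed later by [compute_cpm()] and [compute_fpkm()].
#'
#' @param path Path to a tab-separated file with a header line.
#' @param fraction_label Label of the cellular fraction this table was
#'   quantified from; one of `"whole_cell"`, `"nuclear"`, `"cytosolic"`
#'   (free-form labels are allowed for generic use).
#' @return A `data.frame` with columns `transcript_id`, `expected_count`,
#'   `effective_length`, `fpkm`, `cpm` (the last two `NA` until computed),
#'   one row per transcript, in file order, with attribute `fraction`.
#' @export
read_rsem_quant <- function(path, fraction_label = "whole_cell") {
  if (!file.exists(path)) stop("quantification file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  required <- c("transcript_id", "effective_length", "expected_count")
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0) {
    stop("quantification table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("effective_length", "expected_count")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        stop("non-numeric value in column '", col, "' at data line ",
             bad[1], " of ", path)
      }
      dt[[col]] <- num
    }
  }
  quants <- new_transcript_quant(
    transcript_id = as.character(dt$transcript_id),
    expected_count = dt$expected_count,
    effective_length = dt$effective_length
  )
  attr(quants, "fraction") <- fraction_label
  quants
}

#' Construct a transcript quantification table
#'
#' Low-level constructor used by the reader and the simulator. Enforces the
#' invariants of a quantification vector: unique transcript ids,
#' non-negative counts, positive effective lengths for expressed
#' transcripts.
#'
#' @param transcript_id Character vector of transcript identifiers.
#' @param expected_count Non-negative numeric vector of fragment counts.
#' @param effective_length Numeric vector of effective lengths (nt).
#' @param fpkm,cpm Optional pre-computed normalized units.
#' @return A `data.frame` with the five quantification columns.
#' @export
new_transcript_quant <- function(transcript_id, expected_count,
                                 effective_length,
                                 fpkm = NA_real_, cpm = NA_real_) {
  if (anyDuplicated(transcript_id)) {
    dup <- transcript_id[duplicated(transcript_id)][1]
    stop("duplicated transcript_id in quantification table: ", dup)
  }
  if (any(expected_count < 0, na.rm = TRUE)) {
    stop("negative expected_count")
  }
  bad <- which(expected_count > 0 & effective_length <= 0)
  if (length(bad) > 0) {
    stop("non-positive effective_length with nonzero count for transcript ",
         transcript_id[bad[1]])
  }
  n <- length(transcript_id)
  data.frame(
    transcript_id = as.character(transcript_id),
    expected_count = as.numeric(expected_count),
    effective_length = as.numeric(effective_length),
    fpkm = rep_len(as.numeric(fpkm), n),
    cpm = rep_len(as.numeric(cpm), n),
    stringsAsFactors = FALSE
  )
}

#' Compute counts per million
#'
#' CPM for transcript i is `expected_count(i) / sum(expected_count) * 1e6`.
#' The library size is the sum of expected counts over all rows present, so
#' CPM must be computed before any row filtering (values then stay fixed
#' under subsetting).
#'
#' @param quants Quantification `data.frame` from [read_rsem_quant()].
#' @return The same table with the `cpm` column filled in; CPM sums to 1e6.
#' @export
compute_cpm <- function(quants) {
  total <- sum(quants$expected_count)
  if (total <= 0) stop("all expected counts are zero; CPM undefined")
  quants$cpm <- quants$expected_count / total * 1e6
  quants
}

#' Compute FPKM (fragments per kilobase per million mapped fragments)
#'
#' `fpkm(i) = expected_count(i) * 1e9 / (effective_length(i) * library_size)`.
#' By default the library size is the sum of expected counts over all rows
#' present (pre-filter convention, matching [compute_cpm()]).
#'
#' @param quants Quantification `data.frame`.
#' @param library_size Total mapped fragments; defaults to
#'   `sum(expected_count)`.
#' @return The same table with the `fpkm` column filled in.
#' @export
compute_fpkm <- function(quants, library_size = sum(quants$expected_count)) {
  if (!is.numeric(library_size) || length(library_size) != 1 ||
      library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  bad <- which(quants$expected_count > 0 & quants$effective_length <= 0)
  if (length(bad) > 0) {
    stop("zero effective_length with nonzero count for transcript ",
         quants$transcript_id[bad[1]])
  }
  fpkm <- numeric(nrow(quants))
  nz <- quants$expected_count > 0
  fpkm[nz] <- quants$expected_count[nz] * 1e9 /
    (quants$effective_length[nz] * library_size)
  quants$fpkm <- fpkm
  quants
}

#' Assemble matched per-fraction quantifications for one replicate
#'
#' Intersects transcript ids across the whole-cell, nuclear and cytosolic
#' tables (exact string match, annotation version suffix included) and
#' returns the three tables restricted to the shared transcripts in a
#' common order. Transcripts absent from any fraction are dropped and their
#' count reported via `message()`.
#'
#' @param whole,nuclear,cytosolic Quantification tables for the three
#'   fractions.
#' @param sample_id,replicate_id Identifiers recorded in the result.
#' @return A `FractionQuantSet`: a list with elements `sample_id`,
#'   `replicate_id`, `transcript_id` and `fractions` (named list of the
#'   three aligned tables).
#' @export
assemble_fraction_set <- function(whole, nuclear, cytosolic,
                                  sample_id = "sample",
                                  replicate_id = "rep1") {
  tabs <- list(whole_cell = whole, nuclear = nuclear, cytosolic = cytosolic)
  for (nm in names(tabs)) {
    if (anyDuplicated(tabs[[nm]]$transcript_id)) {
      stop("duplicated transcript_id in ", nm, " table")
    }
  }
  shared <- Reduce(intersect, lapply(tabs, function(t) t$transcript_id))
  if (length(shared) == 0) {
    stop("no transcripts shared across the three fractions")
  }
  n_dropped <- sum(vapply(tabs, nrow, 0L)) - 3L * length(shared)
  if (n_dropped > 0) {
    message("assemble_fraction_set: dropped ", n_dropped,
            " fraction rows absent from at least one fraction")
  }
  aligned <- lapply(tabs, function(t) {
    out <- t[match(shared, t$transcript_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  structure(
    list(sample_id = sample_id, replicate_id = replicate_id,
         transcript_id = shared, fractions = aligned),
    class = "FractionQuantSet"
  )
}

#' @export
print.FractionQuantSet <- function(x, ...) {
  cat("FractionQuantSet:", x$sample_id, "/", x$replicate_id, "\n")
  cat("  transcripts:", length(x$transcript_id), "\n")
  cat("  fractions:", paste(names(x$fractions), collapse = ", "), "\n")
  has_cpm <- !all(is.na(x$fractions$whole_cell$cpm))
  has_fpkm <- !all(is.na(x$fractions$whole_cell$fpkm))
  cat("  cpm computed:", has_cpm, " fpkm computed:", has_fpkm, "\n")
  invisible(x)
}

#' Extract one quantification column across fractions
#'
#' @param fqs A `FractionQuantSet`.
#' @param field Column to extract (`"fpkm"`, `"cpm"`, `"expected_count"`,
#'   `"effective_length"`).
#' @return A numeric matrix, transcripts x fractions.
#' @export
fraction_matrix <- function(fqs, field = "fpkm") {
  stopifnot(inherits(fqs, "FractionQuantSet"))
  m <- vapply(fqs$fractions, function(t) t[[field]],
              numeric(length(fqs$transcript_id)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(fqs$transcript_id),
                                   dimnames = list(NULL, names(fqs$fractions)))
  rownames(m) <- fqs$transcript_id
  m
}

#' Apply compute_cpm / compute_fpkm to every fraction of a set
#'
#' @param fqs A `FractionQuantSet`.
#' @return The set with `cpm` and `fpkm` computed per fraction, each using
#'   that fraction's own total expected count as library size.
#' @export
normalize_fraction_set <- function(fqs) {
  stopifnot(inherits(fqs, "FractionQuantSet"))
  fqs$fractions <- lapply(fqs$fractions,
                          function(t) compute_fpkm(compute_cpm(t)))
  fqs
}

subset_fraction_set <- function(fqs, keep) {
  # keep: logical over transcripts or character ids
  if (is.character(keep)) keep <- fqs$transcript_id %in% keep
  fqs$transcript_id <- fqs$transcript_id[keep]
  fqs$fractions <- lapply(fqs$fractions, function(t) {
    out <- t[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  fqs
}

#' Write / read a FractionQuantSet as tidy TSV
#'
#' The tidy layout has one row per (transcript, fraction) with columns
#' `transcript_id`, `fraction`, `expected_count`, `effective_length`,
#' `cpm`, `fpkm`. Numeric fields survive a round trip at full double
#' precision.
#'
#' @param fqs A `FractionQuantSet`.
#' @param path Output TSV path.
#' @return `write_fraction_set`: the path, invisibly. `read_fraction_set`:
#'   the reconstructed `FractionQuantSet`.
#' @export
write_fraction_set <- function(fqs, path) {
  stopifnot(inherits(fqs, "FractionQuantSet"))
  rows <- lapply(names(fqs$fractions), function(nm) {
    t <- fqs$fractions[[nm]]
    data.frame(transcript_id = t$transcript_id, fraction = nm,
               expected_count = t$expected_count,
               effective_length = t$effective_length,
               cpm = t$cpm, fpkm = t$fpkm, stringsAsFactors = FALSE)
  })
  tidy <- do.call(rbind, rows)
  dt <- data.table::as.data.table(tidy)
  # %.17g keeps full double precision through the text round trip
  for (col in c("expected_count", "effective_length", "cpm", "fpkm")) {
    dt[[col]] <- sprintf("%.17g", dt[[col]])
  }
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_fraction_set
#' @param sample_id,replicate_id Identifiers for the reconstructed set.
#' @export
read_fraction_set <- function(path, sample_id = "sample",
                              replicate_id = "rep1") {
  tidy <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
  tabs <- lapply(split(tidy, tidy$fraction), function(d) {
    new_transcript_quant(d$transcript_id, d$expected_count,
                         d$effective_length, fpkm = as.numeric(d$fpkm),
                         cpm = as.numeric(d$cpm))
  })
  missing <- setdiff(FRACTION_LABELS, names(tabs))
  if (length(missing) > 0) {
    stop("tidy TSV lacks fraction(s): ", paste(missing, collapse = ", "))
  }
  fqs <- assemble_fraction_set(tabs$whole_cell, tabs$nuclear, tabs$cytosolic,
                               sample_id, replicate_id)
  fqs
}

#' Read transcript metadata from a GTF annotation
#'
#' Extracts one metadata record per transcript from the exon (and optional
#' CDS) features of a GTF file: gene id, biotype (attribute
#' `transcript_type`, falling back to `transcript_biotype`), chromosome,
#' strand and the sorted exon intervals (1-based inclusive). Uses
#' \pkg{rtracklayer} when installed, otherwise a small parser for the
#' `key "value"` attribute dialect shared by GENCODE and Ensembl.
#'
#' @param path Path to a GTF file.
#' @return A `data.frame` with columns `transcript_id`, `gene_id`,
#'   `biotype`, `chromosome`, `strand`, and list-columns `exons` and `cds`
#'   (two-column matrices of start/end pairs; `cds` may hold `NULL`).
#' @export
read_gtf_metadata <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    feat <- data.frame(
      chromosome = as.character(df$seqnames),
      feature = as.character(df$type),
      start = df$start, end = df$end,
      strand = as.character(df$strand),
      transcript_id = if ("transcript_id" %in% names(df))
        as.character(df$transcript_id) else NA_character_,
      gene_id = if ("gene_id" %in% names(df))
        as.character(df$gene_id) else NA_character_,
      biotype = gtf_biotype_column(df),
      stringsAsFactors = FALSE
    )
  } else {
    feat <- parse_gtf_lines(readLines(path))
  }
  feat <- feat[feat$feature %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(feat) == 0) stop("GTF contains no exon features: ", path)
  if (any(feat$feature == "exon" & is.na(feat$transcript_id))) {
    stop("exon feature lacking transcript_id attribute in ", path)
  }
  build_transcript_meta(feat)
}

gtf_biotype_column <- function(df) {
  if ("transcript_type" %in% names(df)) return(as.character(df$transcript_type))
  if ("transcript_biotype" %in% names(df)) return(as.character(df$transcript_biotype))
  rep(NA_character_, nrow(df))
}

parse_gtf_lines <- function(lines) {
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, 0L) >= 9
  parts <- parts[ok]
  attr_field <- vapply(parts, `[[`, "", 9)
  get_attr <- function(key) {
    m <- regmatches(attr_field,
                    regexpr(paste0(key, '\\s+"([^"]*)"'), attr_field))
    out <- rep(NA_character_, length(attr_field))
    hit <- vapply(m, length, 0L) > 0
    out[nzchar(m) & !is.na(m)] <- sub(paste0(key, '\\s+"([^"]*)"'), "\\1",
                                      m[nzchar(m)])
    out
  }
  biotype <- get_attr("transcript_type")
  fallback <- get_attr("transcript_biotype")
  biotype[is.na(biotype)] <- fallback[is.na(biotype)]
  data.frame(
    chromosome = vapply(parts, `[[`, "", 1),
    feature = vapply(parts, `[[`, "", 3),
    start = as.integer(vapply(parts, `[[`, "", 4)),
    end = as.integer(vapply(parts, `[[`, "", 5)),
    strand = vapply(parts, `[[`, "", 7),
    transcript_id = get_attr("transcript_id"),
    gene_id = get_attr("gene_id"),
    biotype = biotype,
    stringsAsFactors = FALSE
  )
}

build_transcript_meta <- function(feat) {
  exons <- feat[feat$feature == "exon", , drop = FALSE]
  cds <- feat[feat$feature == "CDS", , drop = FALSE]
  ids <- unique(exons$transcript_id)
  first <- exons[match(ids, exons$transcript_id), , drop = FALSE]
  exon_list <- lapply(ids, function(id) {
    e <- exons[exons$transcript_id == id, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (any(e$start > e$end)) stop("exon with start > end for ", id)
    cbind(start = e$start, end = e$end)
  })
  cds_list <- lapply(ids, function(id) {
    e <- cds[cds$transcript_id == id, , drop = FALSE]
    if (nrow(e) == 0) return(NULL)
    e <- e[order(e$start), , drop = FALSE]
    cbind(start = e$start, end = e$end)
  })
  out <- data.frame(
    transcript_id = ids,
    gene_id = first$gene_id,
    biotype = first$biotype,
    chromosome = first$chromosome,
    strand = first$strand,
    stringsAsFactors = FALSE
  )
  out$exons <- exon_list
  out$cds <- cds_list
  rownames(out) <- NULL
  out
}
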