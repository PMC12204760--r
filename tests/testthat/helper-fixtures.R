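# Fixtures are built in code; nothing is read from disk except files the
# helpers themselves write to tempdir().

make_quant <- function(ids, counts, efflens = rep(1000, length(ids))) {
  new_transcript_quant(ids, counts, efflens)
}

write_quant_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# The two-gene worked example: two cell types, genes A and B of equal
# length, sequenced at depth 1000 per fraction. Returns molecule counts
# and the FractionQuantSet built from exact expected read counts.
fig1_molecules <- function(cell_type) {
  if (cell_type == 1) {
    list(n = c(A = 40, B = 110), c = c(A = 60, B = 90))
  } else {
    list(n = c(A = 40, B = 20), c = c(A = 60, B = 180))
  }
}

fig1_fraction_set <- function(cell_type, depth = 1000, len = 1000) {
  m <- fig1_molecules(cell_type)
  m_w <- m$n + m$c
  lens <- rep(len, 2)
  mk <- function(mol) {
    r <- expected_reads(mol, lens, depth)
    q <- new_transcript_quant(names(mol), r, lens)
    compute_fpkm(compute_cpm(q), library_size = depth)
  }
  assemble_fraction_set(mk(m_w), mk(m$n), mk(m$c),
                        sample_id = paste0("celltype", cell_type))
}

fig1_beta <- function(cell_type, len = 1000) {
  m <- fig1_molecules(cell_type)
  m_w <- m$n + m$c
  sum(m$c * len) / sum(m_w * len)
}

# quantification set with prescribed per-fraction fpkm (for unit tests on
# filters / LI that do not care about counts)
make_fqs <- function(ids, cpm_w = NULL, cpm_n = NULL, cpm_c = NULL,
                     fpkm_w = NULL, fpkm_n = NULL, fpkm_c = NULL) {
  n <- length(ids)
  blank <- function(fpkm, cpm) {
    q <- new_transcript_quant(ids, rep(1, n), rep(1000, n))
    q$fpkm <- if (is.null(fpkm)) rep(1, n) else fpkm
    q$cpm <- if (is.null(cpm)) rep(1, n) else cpm
    q
  }
  assemble_fraction_set(blank(fpkm_w, cpm_w), blank(fpkm_n, cpm_n),
                        blank(fpkm_c, cpm_c))
}

make_li_table <- function(ids, li, beta = 0.7) {
  out <- data.frame(transcript_id = ids, li = li, naive_li = li,
                    class_label = "unassigned", stringsAsFactors = FALSE)
  attr(out, "beta_used") <- beta
  class(out) <- c("LocalizationTable", "data.frame")
  out
}

tiny_gtf <- function(path = tempfile(fileext = ".gtf")) {
  lines <- c(
    'chr1\tTEST\ttranscript\t100\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; transcript_type "protein_coding";',
    # exons deliberately unsorted
    'chr1\tTEST\texon\t300\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; transcript_type "protein_coding";',
    'chr1\tTEST\texon\t100\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; transcript_type "protein_coding";',
    'chr1\tTEST\tCDS\t150\t350\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; transcript_type "protein_coding";',
    'chrM\tTEST\texon\t10\t500\t.\t-\t.\tgene_id "G2"; transcript_id "T2"; transcript_type "Mt_rRNA";'
  )
  writeLines(lines, path)
  path
}

# brute-force upper-tail hypergeometric by subset enumeration (N <= 12)
hyper_tail_enum <- function(k, K, N, n) {
  sets <- utils::combn(N, n)
  hits <- colSums(sets <= K)  # elements 1..K are the "hit" population
  mean(hits >= k)
}
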