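# Config-driven end-to-end pipeline:
# (simulate | read quant) -> normalize -> filters -> beta per replicate ->
# high-beta exclusion -> LI per replicate -> average -> classify,
# with a JSON provenance manifest alongside every run.

#' Read a flat key = value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values that
#' parse as numbers become numeric, `true`/`false` become logical.
#'
#' @param path Path to the config file.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[[`, "", 2)
  vals <- trimws(vapply(kv, `[[`, "", 3))
  vals <- gsub('^"|"$', "", vals)
  out <- lapply(vals, function(v) {
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

pipeline_defaults <- function() {
  list(mode = "quant", replicates = 1, cpm_threshold = 1,
       beta_cutoff = 0.95, scheme = "threshold_04_06",
       chains = 4, draws = 6000, warmup = 2000, adapt_delta = 0.9,
       max_treedepth = 10, seed = 1, sample_id = "sample",
       dai_filter = FALSE,
       # simulate mode
       n_transcripts = 5000, molecules = 1e5, beta = 0.7, depth = 1e6)
}

validate_pipeline_config <- function(config) {
  config <- utils::modifyList(pipeline_defaults(), config)
  if (!config$mode %in% c("quant", "simulate")) {
    stop("config error: mode must be 'quant' or 'simulate'")
  }
  if (config$mode == "quant") {
    for (r in seq_len(config$replicates)) {
      for (fr in c("whole", "nuclear", "cytosolic")) {
        key <- paste0(fr, "_", r)
        if (is.null(config[[key]])) {
          stop("config error: missing path '", key, "' for replicate ", r)
        }
        if (!file.exists(config[[key]])) {
          stop("input file not found: ", config[[key]])
        }
      }
    }
  }
  if (!is.null(config$gtf) && !file.exists(config$gtf)) {
    stop("input file not found: ", config$gtf)
  }
  stopifnot(config$beta_cutoff > 0, config$beta_cutoff <= 1,
            config$warmup < config$draws)
  config
}

#' Run the full localization pipeline
#'
#' Executes preprocessing, per-replicate beta estimation, high-beta sample
#' exclusion, per-replicate LI computation, replicate averaging and
#' classification, writing TSV outputs and a JSON provenance manifest to
#' `out`.
#'
#' @param config Path to a flat `key = value` config file (see
#'   [read_pipeline_config()]) or an equivalent named list. Keys: `mode`
#'   (`"quant"` or `"simulate"`); `whole_1`/`nuclear_1`/`cytosolic_1` etc.
#'   input TSVs in quant mode; `n_transcripts`, `molecules`, `beta`,
#'   `depth` in simulate mode; `gtf` (optional, enables the mitochondrial
#'   filter); `cpm_threshold`, `beta_cutoff`, `scheme`, `dai_filter`;
#'   sampler settings `chains`, `draws`, `warmup`, `adapt_delta`,
#'   `max_treedepth`, `seed`.
#' @param out Output directory (created if needed).
#' @return Invisibly, a list with `beta` (per replicate), `retained`
#'   replicate names, the classified `LocalizationTable`, and the
#'   manifest path.
#' @export
run_pipeline <- function(config, out) {
  config_path <- NA_character_
  if (is.character(config) && length(config) == 1) {
    config_path <- config
    config <- read_pipeline_config(config)
  }
  config <- validate_pipeline_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  reps <- list()
  truth <- NULL
  if (config$mode == "simulate") {
    sc <- sim_config(n_transcripts = config$n_transcripts,
                     total_molecules = config$molecules,
                     target_beta = config$beta, depth = config$depth,
                     seed = as.integer(config$seed))
    sim <- simulate_fraction_dataset(sc, out = file.path(out, "simulated"))
    reps[["rep1"]] <- sim$fqs
    truth <- sim$truth
  } else {
    for (r in seq_len(config$replicates)) {
      rid <- paste0("rep", r)
      reps[[rid]] <- assemble_fraction_set(
        read_rsem_quant(config[[paste0("whole_", r)]], "whole_cell"),
        read_rsem_quant(config[[paste0("nuclear_", r)]], "nuclear"),
        read_rsem_quant(config[[paste0("cytosolic_", r)]], "cytosolic"),
        sample_id = config$sample_id, replicate_id = rid)
    }
  }

  meta <- if (!is.null(config$gtf)) read_gtf_metadata(config$gtf) else NULL
  reps <- lapply(reps, function(fqs) {
    fqs <- normalize_fraction_set(fqs)
    fqs <- filter_by_cpm(fqs, threshold = config$cpm_threshold)
    if (!is.null(meta)) fqs <- filter_mitochondrial(fqs, meta)
    if (isTRUE(config$dai_filter)) fqs <- dai_outlier_filter(fqs)
    fqs
  })
  reps <- filter_replicate_presence(reps)

  bm_config <- beta_model_config(chains = config$chains,
                                 draws_per_chain = config$draws,
                                 warmup = config$warmup,
                                 adapt_delta = config$adapt_delta,
                                 max_treedepth = config$max_treedepth,
                                 seed = as.integer(config$seed))
  posteriors <- lapply(reps, function(fqs) {
    fpkm <- fraction_matrix(fqs, "fpkm")
    estimate_beta_bayes(fpkm[, "whole_cell"], fpkm[, "nuclear"],
                        fpkm[, "cytosolic"], bm_config)
  })
  beta_hat <- vapply(posteriors, `[[`, 0, "map_estimate")

  retained <- exclude_high_beta_samples(beta_hat, cutoff = config$beta_cutoff)
  tables <- lapply(retained, function(rid) {
    li_table(reps[[rid]], beta_hat[[rid]])
  })
  names(tables) <- retained

  final <- NULL
  if (length(tables) > 0) {
    final <- average_li_across_replicates(unname(tables))
    final <- classify_localization(final, scheme = config$scheme)
    write_li_table(final, file.path(out, "localization.tsv"))
  }
  for (rid in names(reps)) {
    write_fraction_set(reps[[rid]],
                       file.path(out, paste0("quant_", rid, ".tsv")))
  }

  manifest <- list(
    package = "RNAfrac",
    version = as.character(utils::packageVersion("RNAfrac")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config,
    config_file = config_path,
    config_md5 = if (!is.na(config_path)) unname(tools::md5sum(config_path))
                 else NA_character_,
    beta_estimates = as.list(beta_hat),
    beta_rhat = lapply(posteriors,
                       function(p) unname(p$diagnostics$rhat["beta"])),
    divergences = lapply(posteriors, `[[`, "divergence_count"),
    retained_replicates = retained,
    excluded_replicates = setdiff(names(beta_hat), retained),
    n_transcripts = lapply(reps, function(f) length(f$transcript_id))
  )
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")

  invisible(list(beta = beta_hat, retained = retained,
                 posteriors = posteriors,
                 localization = final, truth = truth,
                 manifest = manifest_path))
}
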