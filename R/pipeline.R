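# End-to-end orchestration: simulate -> demultiplex -> filter -> cluster ->
# classify -> report, from a single validated config, with every
# intermediate written as plain text and a manifest recording seeds, the
# config hash and stage counts. Re-running with the same config reproduces
# byte-identical TSV outputs.

.SCHEMA_VERSION <- 1L

.CONFIG_KEYS <- list(
  top = c("schema_version", "simulation", "processing", "stats"),
  simulation = c("community", "n_templates", "n_divergent", "amplicon_length",
                 "within_group_substitutions", "divergent_substitutions",
                 "region", "mid", "mismatch_spec", "tiers",
                 "pcr_cycles", "base_efficiency", "per_mismatch_penalty",
                 "three_prime_extra_penalty", "chimera_rate",
                 "n_chimera_species", "contamination_rate",
                 "substitution_rate", "homopolymer_indel_base_rate",
                 "ambiguous_call_rate", "truncation_rate", "n_reads", "seed",
                 "deterministic_counts"),
  processing = c("filter", "trim_length", "precluster", "precluster_width",
                 "precluster_min_size", "clustering", "identity", "cutoff",
                 "allow_premature", "min_prefix"),
  stats = c("B", "near_match_cutoff", "bootstrap_target_size"))

#' Default pipeline configuration
#'
#' The canonical study conditions: 20 templates (19 similar + 1 divergent),
#' tiered abundances spanning 0.18 down to 1e-5, 30 PCR cycles, sub-1%
#' chimera and contamination rates, and per-base error rates summing to
#' under 0.5%.
#'
#' @param seed root seed for the run.
#' @param n_reads reads to simulate.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1, n_reads = 10000) {
  list(
    schema_version = .SCHEMA_VERSION,
    simulation = list(
      community = "tiered", n_templates = 20L, n_divergent = 1L,
      amplicon_length = 250L, within_group_substitutions = 5L,
      divergent_substitutions = 40L, region = "v3v4", mid = "ACGTACGTAC",
      mismatch_spec = list(),
      pcr_cycles = 30L, base_efficiency = 0.9, per_mismatch_penalty = 0.85,
      three_prime_extra_penalty = 0.7, chimera_rate = 0.005,
      n_chimera_species = 5L, contamination_rate = 0.005,
      substitution_rate = 0.003, homopolymer_indel_base_rate = 0.001,
      ambiguous_call_rate = 0.0005, truncation_rate = 0,
      n_reads = as.integer(n_reads), seed = as.integer(seed),
      deterministic_counts = FALSE),
    processing = list(
      filter = "slp", trim_length = 216L, precluster = TRUE,
      precluster_width = 0.02, precluster_min_size = 10L,
      clustering = "average_neighbor", identity = 0.97, cutoff = 0.03,
      allow_premature = FALSE, min_prefix = NULL),
    stats = list(B = 1000L, near_match_cutoff = 0.03,
                 bootstrap_target_size = NULL))
}

#' Validate a pipeline configuration
#'
#' Unknown keys are errors (frozen schema) so config drift fails loudly.
#'
#' @param config nested configuration list.
#' @return the config, invisibly, after validation.
#' @export
validate_run_config <- function(config) {
  chk <- function(got, allowed, where) {
    extra <- setdiff(names(got), allowed)
    if (length(extra)) {
      stop("unknown config key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
    }
  }
  chk(config, .CONFIG_KEYS$top, "top level")
  if (!identical(as.integer(config$schema_version), .SCHEMA_VERSION)) {
    stop("unsupported config schema_version: ", config$schema_version)
  }
  chk(config$simulation, .CONFIG_KEYS$simulation, "simulation")
  chk(config$processing, .CONFIG_KEYS$processing, "processing")
  chk(config$stats, .CONFIG_KEYS$stats, "stats")
  stopifnot(config$simulation$community %in% c("equal", "tiered"),
            config$processing$filter %in% c("slp", "fixed_length", "none"),
            config$processing$clustering %in% c("greedy", "average_neighbor"))
  invisible(config)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$simulation$mismatch_spec)) {
    cfg$simulation$mismatch_spec <- list()
  }
  validate_run_config(cfg)
  cfg
}

.sim_config_from <- function(s) {
  sim_config(pcr_cycles = s$pcr_cycles, base_efficiency = s$base_efficiency,
             per_mismatch_penalty = s$per_mismatch_penalty,
             three_prime_extra_penalty = s$three_prime_extra_penalty,
             chimera_rate = s$chimera_rate,
             n_chimera_species = s$n_chimera_species,
             contamination_rate = s$contamination_rate,
             substitution_rate = s$substitution_rate,
             homopolymer_indel_base_rate = s$homopolymer_indel_base_rate,
             ambiguous_call_rate = s$ambiguous_call_rate,
             truncation_rate = s$truncation_rate,
             n_reads = s$n_reads, seed = s$seed,
             deterministic_counts = isTRUE(s$deterministic_counts))
}

#' Run the full simulate/process/classify/report pipeline
#'
#' Every intermediate is written under `outdir` (FASTA/FASTQ/TSV/JSON only);
#' a manifest records the config hash, seeds and stage counts. The function
#' also returns all results in memory.
#'
#' @param config configuration list (see [default_run_config()]).
#' @param outdir output directory (created).
#' @return list: references, profile, pool, chimeras, reads, truth,
#'   demux, filtered, uniques, otus, classified, stats, manifest.
#' @export
run_pipeline <- function(config, outdir) {
  validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  s <- config$simulation
  p <- config$processing
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  counts <- list()
  primer_pair <- default_primer_pair(s$region)

  refs <- stage("references", build_reference_set(
    n_templates = s$n_templates, n_divergent = s$n_divergent,
    amplicon_length = s$amplicon_length,
    within_group_substitutions = s$within_group_substitutions,
    divergent_substitutions = s$divergent_substitutions,
    primer_pair = primer_pair, mismatch_spec = s$mismatch_spec,
    seed = stage_seed(s$seed, "references")))
  profile <- make_profile(s$community, names(refs), tiers = s$tiers)
  contaminants <- make_contaminant_set(
    n = 1, length = s$amplicon_length,
    seed = stage_seed(s$seed, "contaminants"))

  simcfg <- .sim_config_from(s)
  pool <- stage("pcr", simulate_pcr(refs, profile, primer_pair, simcfg))
  ch <- stage("chimeras", simulate_chimeras(
    pool, refs, simcfg$chimera_rate, simcfg$n_chimera_species,
    seed = stage_seed(s$seed, "chimeras")))
  sim <- stage("reads", simulate_reads(
    ch$pool, refs, simcfg, mid = s$mid, primer_pair = primer_pair,
    chimeras = ch$chimeras, contaminants = contaminants))
  counts$simulated <- nrow(sim$reads)

  # write simulation outputs
  write_sequences(sim$reads, file.path(outdir, "reads.fastq"), "fastq")
  write_sequences(
    seq_records(names(refs), vapply(refs, `[[`, character(1), "amplicon")),
    file.path(outdir, "references.fasta"), "fasta")
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(template_id = names(profile), expected = as.numeric(profile)),
    file.path(outdir, "profile.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # demultiplex
  mids <- data.frame(mid = s$mid, sample_id = "sample1",
                     stringsAsFactors = FALSE)
  dm <- stage("demultiplex",
              demultiplex_and_trim(sim$reads, mids, primer_pair$forward))
  assigned <- dm$samples$sample1
  counts$assigned <- nrow(assigned)
  counts$discarded <- nrow(dm$discarded)

  # error-free identification on all assigned reads (pre-filter)
  ef <- stage("error_free", identify_error_free(
    assigned, refs, allow_premature = isTRUE(p$allow_premature),
    min_prefix = p$min_prefix))
  counts$error_free <- sum(ef$matches$match_kind != "none")
  utils::write.table(ef$frequencies,
                     file.path(outdir, "error_free_frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # quality filter
  filt <- stage("filter", switch(p$filter,
    slp = filter_slp_style(assigned),
    fixed_length = filter_fixed_length(assigned, p$trim_length),
    none = list(kept = assigned,
                discarded = data.frame(read_id = character(),
                                       reason = character()))))
  counts$filtered_kept <- nrow(filt$kept)
  utils::write.table(filt$discarded, file.path(outdir, "filter_discards.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # dereplicate / precluster / cluster
  uniq <- stage("dereplicate", dereplicate(filt$kept))
  counts$uniques <- nrow(uniq)
  if (isTRUE(p$precluster)) {
    uniq <- stage("precluster", precluster_single_linkage(
      uniq, width = p$precluster_width,
      min_cluster_size = p$precluster_min_size))
    counts$preclustered_uniques <- nrow(uniq)
  }
  otus <- stage("cluster", switch(p$clustering,
    greedy = cluster_greedy(uniq, identity = p$identity),
    average_neighbor = cluster_average_neighbor(uniq, cutoff = p$cutoff)))
  counts$otus <- length(otus)
  write_otu_table(otus, file.path(outdir, "otus.tsv"))

  # classify
  classified <- stage("classify", classify_otus(
    otus, refs, contaminant_set = contaminants, truth = sim$truth,
    near_match_cutoff = config$stats$near_match_cutoff,
    allow_premature = isTRUE(p$allow_premature)))
  utils::write.table(classified, file.path(outdir, "classified_otus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rf <- rank_frequency_report(classified, profile)
  utils::write.table(rf, file.path(outdir, "rank_frequency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # recovery statistics on error-free frequencies vs input profile
  obs <- setNames(ef$frequencies$frequency, ef$frequencies$template_id)
  keep <- obs > 0 & profile > 0
  stats_out <- list(
    spearman_rho = if (sum(keep) >= 3)
      spearman_rho(obs[keep], profile[keep]) else NA_real_,
    loglog_pearson_r = if (sum(keep) >= 3)
      as.numeric(loglog_pearson(obs[keep], profile[keep])) else NA_real_,
    n_compared = sum(keep),
    chao1 = chao1(vapply(otus, `[[`, numeric(1), "total_abundance")),
    clustering_control = clustering_control(
      refs, method = p$clustering, identity = p$identity, cutoff = p$cutoff))
  oet <- oe_table(obs, profile)
  utils::write.table(oet, file.path(outdir, "oe_ratios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mm <- vapply(refs, function(t)
    template_primer_mismatches(t, primer_pair)$total, numeric(1))
  stats_out$mismatch_tests <- if (length(unique(mm)) > 1) {
    tryCatch(mismatch_effect_tests(mm, setNames(oet$oe_ratio, oet$template_id)),
             error = function(e) NULL)
  } else NULL
  if (!is.null(config$stats$bootstrap_target_size)) {
    efpool <- ef$matches$matched_template[ef$matches$match_kind != "none"]
    stats_out$bootstrap <- bootstrap_correlations(
      efpool, profile, target_size = config$stats$bootstrap_target_size,
      B = config$stats$B, seed = stage_seed(s$seed, "bootstrap"))
  }
  cat_counts <- table(factor(classified$category,
                             levels = c("true", "miscalled", "near_match",
                                        "contamination", "chimeric",
                                        "false_derived")))
  summary_df <- data.frame(
    metric = c("total_otu", "chao1", names(cat_counts), "clustering_control",
               "spearman_rho", "loglog_pearson_r"),
    value = c(length(otus), stats_out$chao1, as.numeric(cat_counts),
              stats_out$clustering_control, stats_out$spearman_rho,
              stats_out$loglog_pearson_r),
    stringsAsFactors = FALSE)
  utils::write.table(summary_df, file.path(outdir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # manifest
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  manifest <- list(
    schema_version = .SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("mockamp")),
    seed = s$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(references = refs, profile = profile, pool = pool,
                 chimeras = ch$chimeras, reads = sim$reads,
                 truth = sim$truth, demux = dm, error_free = ef,
                 filtered = filt, uniques = uniq, otus = otus,
                 classified = classified, stats = stats_out,
                 manifest = manifest))
}

#' Clustering controls for every configured method
#'
#' @param config configuration list.
#' @return named integer vector of OTU counts per method.
#' @export
run_clustering_control <- function(config) {
  validate_run_config(config)
  s <- config$simulation
  refs <- build_reference_set(
    n_templates = s$n_templates, n_divergent = s$n_divergent,
    amplicon_length = s$amplicon_length,
    within_group_substitutions = s$within_group_substitutions,
    divergent_substitutions = s$divergent_substitutions,
    primer_pair = default_primer_pair(s$region),
    mismatch_spec = s$mismatch_spec,
    seed = stage_seed(s$seed, "references"))
  c(greedy = clustering_control(refs, "greedy",
                                identity = config$processing$identity),
    average_neighbor = clustering_control(
      refs, "average_neighbor", cutoff = config$processing$cutoff))
}
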