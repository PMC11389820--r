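#' Pipeline configuration
#'
#' Collects every threshold the pipeline applies, the planted design of the
#' synthetic screen, and the generator settings for the integration stage.
#' Unknown keys are rejected; every threshold is checked against its domain.
#'
#' @param alpha Per-round screen significance level, in (0, 1) (default 0.05).
#' @param min_delta Minimum |inclusion-level difference| for a significant
#'   splicing event (strict; default 0.05).
#' @param max_fdr FDR ceiling for splicing events (strict; default 0.05).
#' @param min_reads Minimum total junction reads per event (default 150).
#' @param tpm_threshold Expression threshold (default 10).
#' @param direction Screen direction: `"greater"` tests for induced
#'   inclusion, `"less"` for induced skipping.
#' @param seed Master seed; all stage seeds are derived from it.
#' @param n_30D_only,n_30U_only,n_both,n_null Planted screen design: counts
#'   of constructs that respond on one reporter, on both, or not at all.
#' @param delta_psi Planted effect size of responsive constructs (default 0.3).
#' @param noise_cv Luminescence noise CV (default 0.02).
#' @param n_genes,bound_gene_or,kd_delta Integration-stage generator
#'   settings.
#' @param outdir Output directory for stage tables and the summary JSON.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(alpha = 0.05, min_delta = 0.05, max_fdr = 0.05,
                            min_reads = 150, tpm_threshold = 10,
                            direction = "greater", seed = 7L,
                            n_30D_only = 10L, n_30U_only = 5L, n_both = 5L,
                            n_null = 0L, delta_psi = 0.3, noise_cv = 0.02,
                            n_genes = 500L, bound_gene_or = 4, kd_delta = 0.3,
                            outdir = tempfile("tetherscreen_run_")) {
  chk <- function(ok, msg) if (!ok) stop_invalid_config(msg)
  chk(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  chk(is.numeric(min_delta) && min_delta >= 0 && min_delta < 1,
      "min_delta must lie in [0, 1)")
  chk(is.numeric(max_fdr) && max_fdr > 0 && max_fdr <= 1,
      "max_fdr must lie in (0, 1]")
  chk(is_count(min_reads), "min_reads must be a non-negative integer")
  chk(is.numeric(tpm_threshold) && tpm_threshold >= 0, "tpm_threshold must be >= 0")
  chk(direction %in% c("greater", "less"), "direction must be 'greater' or 'less'")
  chk(is_count(seed), "seed must be a non-negative integer")
  chk(is_count(n_30D_only) && is_count(n_30U_only) && is_count(n_both) &&
        is_count(n_null), "planted counts must be non-negative integers")
  chk(n_30D_only + n_30U_only + n_both + n_null > 0, "design must contain constructs")
  chk(is_fraction(delta_psi), "delta_psi must lie in [0, 1]")
  chk(is.numeric(noise_cv) && noise_cv >= 0, "noise_cv must be >= 0")
  chk(is_count(n_genes, min = 1L), "n_genes must be >= 1")
  chk(is.numeric(bound_gene_or) && bound_gene_or > 0, "bound_gene_or must be > 0")
  chk(is_fraction(kd_delta), "kd_delta must lie in [0, 1]")
  structure(
    list(alpha = alpha, min_delta = min_delta, max_fdr = max_fdr,
         min_reads = min_reads, tpm_threshold = tpm_threshold,
         direction = direction, seed = as.integer(seed),
         n_30D_only = as.integer(n_30D_only),
         n_30U_only = as.integer(n_30U_only), n_both = as.integer(n_both),
         n_null = as.integer(n_null), delta_psi = delta_psi,
         noise_cv = noise_cv, n_genes = as.integer(n_genes),
         bound_gene_or = bound_gene_or, kd_delta = kd_delta, outdir = outdir),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected rather than ignored.
#'
#' @param path Path to the YAML file.
#' @return A validated `"pipeline_config"`.
#' @export
pipeline_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0L) {
    stop_invalid_config(paste("unknown configuration key(s):",
                              paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Planted two-reporter screen design
#'
#' Builds the per-construct true response table of a synthetic screen:
#' `n_30D_only` constructs respond only when tethered downstream,
#' `n_30U_only` only upstream, `n_both` on both reporters, and `n_null` on
#' neither.
#'
#' @param n_30D_only,n_30U_only,n_both,n_null Construct counts per class.
#' @param delta_psi Planted true psi of a responsive construct (default 0.3).
#' @return Data frame with columns `construct_id`, `psi_30D`, `psi_30U`,
#'   `planted_class`.
#' @export
planted_design <- function(n_30D_only = 10L, n_30U_only = 5L, n_both = 5L,
                           n_null = 0L, delta_psi = 0.3) {
  cls <- rep(c("30D_only", "30U_only", "both", "non_hit"),
             times = c(n_30D_only, n_30U_only, n_both, n_null))
  n <- length(cls)
  if (n == 0L) stop_invalid_config("design must contain at least one construct")
  data.frame(
    construct_id = sprintf("RBP%04d", seq_len(n)),
    psi_30D = ifelse(cls %in% c("30D_only", "both"), delta_psi, 0),
    psi_30U = ifelse(cls %in% c("30U_only", "both"), delta_psi, 0),
    planted_class = cls,
    stringsAsFactors = FALSE
  )
}

#' Simulate and analyse a complete two-reporter screen
#'
#' Runs the whole experimental workflow on synthetic data: round-1 screens of
#' every construct on both reporters, an independent round-2 replication of
#' the round-1 passers, gel validation of the round-2 passers with a
#' Bonferroni gate, and a cross-reporter retest of hits exclusive to one
#' reporter. Every stage draws from its own seed stream derived from
#' `config$seed`, so the full run is reproducible.
#'
#' @param design A [planted_design()] table (`construct_id`, `psi_30D`,
#'   `psi_30U`).
#' @param config A [simulation_config()]; its seed drives all stages.
#' @param alpha Per-round significance level (default 0.05).
#' @param direction Test direction (default `"greater"`).
#' @param gel_noise_cv Band-intensity noise CV (default `config$noise_cv`).
#' @param gel_control_psi RNA-level baseline inclusion of gel controls
#'   (default 0.05).
#' @return List: `cascade` (the [run_cascade()] result), `psi` (named list of
#'   round-1 psi tables per reporter), and `stage_tables` (round/gel/retest
#'   call tables).
#' @export
run_synthetic_screen <- function(design, config = simulation_config(),
                                 alpha = 0.05, direction = "greater",
                                 gel_noise_cv = NULL, gel_control_psi = 0.05) {
  require_columns(design, c("construct_id", "psi_30D", "psi_30U"),
                  "screen design")
  if (is.null(gel_noise_cv)) gel_noise_cv <- max(config$noise_cv, 0.01)
  reporters <- c("30D", "30U")
  truth <- list(
    "30D" = screen_truth(stats::setNames(design$psi_30D, design$construct_id), "30D"),
    "30U" = screen_truth(stats::setNames(design$psi_30U, design$construct_id), "30U")
  )
  reconfig <- function(stream) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, stream)
    class(cfg) <- "simulation_config"
    cfg
  }
  round_call <- function(rp, stream) {
    cfg <- reconfig(stream)
    psi <- estimate_psi_table(simulate_screen(truth[[rp]], cfg))
    list(psi = psi, calls = call_round(psi, alpha = alpha, direction = direction))
  }
  r1 <- list("30D" = round_call("30D", 1L), "30U" = round_call("30U", 2L))
  r2_full <- list("30D" = round_call("30D", 3L), "30U" = round_call("30U", 4L))

  round1 <- lapply(r1, `[[`, "calls")
  round2 <- lapply(reporters, function(rp) {
    passers <- round1[[rp]]$construct_id[round1[[rp]]$pass]
    calls <- r2_full[[rp]]$calls
    calls[calls$construct_id %in% passers, , drop = FALSE]
  })
  names(round2) <- reporters

  gel <- lapply(reporters, function(rp) {
    survivors <- round2[[rp]]$construct_id[round2[[rp]]$pass]
    if (length(survivors) == 0L) {
      return(data.frame(construct_id = character(), n_lanes = integer(),
                        mean_ratio = numeric(), p_value = numeric(),
                        alpha_bonferroni = numeric(), pass = logical(),
                        note = character(), stringsAsFactors = FALSE))
    }
    lanes <- simulate_gel(survivors, truth[[rp]], noise_cv = gel_noise_cv,
                          control_psi = gel_control_psi,
                          seed = derive_seed(config$seed, 5L + (rp == "30U")))
    gel_validation(lanes, control_construct_ids = "GEL_CONTROL",
                   alpha = alpha, direction = direction)
  })
  names(gel) <- reporters

  hit_of <- function(rp) {
    ids <- round1[[rp]]$construct_id
    p1 <- round1[[rp]]$pass
    p2 <- ids %in% round2[[rp]]$construct_id[round2[[rp]]$pass]
    pg <- ids %in% gel[[rp]]$construct_id[gel[[rp]]$pass]
    ids[p1 & p2 & pg]
  }
  hits <- lapply(reporters, hit_of)
  names(hits) <- reporters
  retest <- list("30D" = NULL, "30U" = NULL)
  for (rp in reporters) {
    other <- setdiff(reporters, rp)
    excl <- setdiff(hits[[other]], hits[[rp]])
    if (length(excl) == 0L) next
    psi_col <- paste0("psi_", rp)
    sub_truth <- screen_truth(
      stats::setNames(design[[psi_col]][match(excl, design$construct_id)], excl),
      reporter_id = rp
    )
    cfg <- reconfig(7L + (rp == "30U"))
    psi <- estimate_psi_table(simulate_screen(sub_truth, cfg))
    retest[[rp]] <- call_round(psi, alpha = alpha, direction = direction)
  }

  cascade <- run_cascade(round1, round2, gel, retest, alpha = alpha)
  list(cascade = cascade,
       psi = list("30D" = r1[["30D"]]$psi, "30U" = r1[["30U"]]$psi),
       stage_tables = list(round1 = round1, round2 = round2, gel = gel,
                           retest = retest))
}

#' Run the full synthetic pipeline and write a report bundle
#'
#' Executes simulate -> psi -> cascade -> integrate with the thresholds in
#' `config`, writes every stage table under `config$outdir` (psi TSV, hit
#' calls TSV, BED windows, skipped-exon TSV, TPM TSV, positional-map TSV)
#' plus a `summary.json` recording the thresholds applied, per-stage record
#' tallies, final hit-category counts and the binding-enrichment statistics.
#' Identical configuration implies an identical bundle.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid_config("config must come from pipeline_config()")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)

  design <- planted_design(config$n_30D_only, config$n_30U_only,
                           config$n_both, config$n_null, config$delta_psi)
  sim_cfg <- simulation_config(noise_cv = config$noise_cv, seed = config$seed)
  screen <- run_synthetic_screen(design, sim_cfg, alpha = config$alpha,
                                 direction = config$direction)
  write_psi_table(screen$psi[["30D"]], out("psi_30D.tsv"))
  write_psi_table(screen$psi[["30U"]], out("psi_30U.tsv"))
  utils::write.table(screen$cascade$hit_calls, out("hit_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  loci <- simulate_locus_set(config$n_genes,
                             seed = derive_seed(config$seed, 11L))
  tabs <- simulate_integration_tables(loci, bound_gene_or = config$bound_gene_or,
                                      kd_delta = config$kd_delta,
                                      seed = derive_seed(config$seed, 12L))
  write_bed_windows(tabs$windows, out("enriched_windows.bed"))
  write_se_table(tabs$events, out("se_events.tsv"))
  write_tpm_table(tabs$tpm, out("tpm.tsv"))

  windows <- read_bed_windows(out("enriched_windows.bed"))
  events <- read_se_table(out("se_events.tsv"))
  tpm <- read_tpm_table(out("tpm.tsv"))
  sig <- filter_se_events(events, config$min_delta, config$max_fdr,
                          config$min_reads)
  expressed <- expressed_gene_set(tpm, config$tpm_threshold, inclusive = TRUE)
  enrich <- bound_fraction_enrichment(windows, unique(sig$GeneID), expressed)
  pmap <- positional_map(windows, sig)
  utils::write.table(pmap[, c("event_id", "feature", "transcript_position",
                              "delta_psi")],
                     out("positional_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  summary <- list(
    thresholds = list(alpha = config$alpha, min_delta = config$min_delta,
                      max_fdr = config$max_fdr, min_reads = config$min_reads,
                      tpm_threshold = config$tpm_threshold,
                      direction = config$direction),
    seed = config$seed,
    screen = list(
      n_constructs = nrow(design),
      category_counts = as.list(screen$cascade$counts),
      round1_passed = list(
        "30D" = sum(screen$stage_tables$round1[["30D"]]$pass),
        "30U" = sum(screen$stage_tables$round1[["30U"]]$pass)
      )
    ),
    integration = list(
      n_genes = config$n_genes,
      n_events_input = nrow(events),
      n_events_significant = nrow(sig),
      n_expressed_genes = length(expressed),
      odds_ratio = enrich$odds_ratio,
      fisher_p = enrich$p_value,
      fraction_bound_sensitive = enrich$fraction_bound_sensitive,
      fraction_bound_insensitive = enrich$fraction_bound_insensitive,
      n_positional_points = nrow(pmap)
    )
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(summary)
}
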