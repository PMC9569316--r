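# Pipeline orchestration: a single validated configuration drives either a
# fully simulated run (with ground truth written alongside) or a run on
# user-supplied TSV inputs, through all analysis stages, writing one TSV
# per stage plus a summary of headline counts.

#' Build and validate a pipeline configuration
#'
#' @param out_dir directory for stage outputs (created if missing).
#' @param simulate generate inputs with the synthetic-data module (TRUE) or
#'   read them from `paths` (FALSE).
#' @param seed master seed; every stochastic step derives its stream from
#'   it.
#' @param n_proteins,n_metabolites,rewire_rate simulated-world size
#'   (simulate mode).
#' @param config a [sim_config()] describing the experiment geometry.
#' @param paths named list of input files for `simulate = FALSE`:
#'   `profiles`, `itsa`, `abundance`, `samples`.
#' @param fdr_abundance,fdr_stability,fdr_totals per-analysis FDR
#'   thresholds.
#' @param fc_threshold fold-change threshold (linear scale).
#' @param md_factor Manhattan-distance threshold multiplier.
#' @param pcc_threshold network edge threshold.
#' @param min_rel_height peak-deconvolution relative height cut-off.
#' @param cut_height Ward dendrogram cut height (used when a dipeptide
#'   distance matrix is supplied).
#' @param n_permutations dis-elution permutation budget.
#' @param dipeptide_groups optional named vector metabolite id -> group;
#'   default: metabolite class tags.
#' @param pathway_groups optional named list pathway -> protein ids;
#'   default: one group containing every protein.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("secshift_run_"),
                            simulate = TRUE,
                            seed = 1L,
                            n_proteins = 60L,
                            n_metabolites = 30L,
                            rewire_rate = 0.2,
                            config = sim_config(),
                            paths = list(),
                            fdr_abundance = 0.01,
                            fdr_stability = 0.01,
                            fdr_totals = 0.05,
                            fc_threshold = 2,
                            md_factor = 1.5,
                            pcc_threshold = 0.7,
                            min_rel_height = 0.10,
                            cut_height = 1.6,
                            n_permutations = 1000L,
                            dipeptide_groups = NULL,
                            pathway_groups = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- assert_count(seed, "seed", 0L)
  for (nm in c("fdr_abundance", "fdr_stability", "fdr_totals"))
    assert_scalar_number(get(nm), nm, 0, 1)
  assert_scalar_number(fc_threshold, "fc_threshold", lower = 1)
  assert_scalar_number(md_factor, "md_factor", lower = 0)
  assert_scalar_number(pcc_threshold, "pcc_threshold", -1, 1)
  assert_scalar_number(min_rel_height, "min_rel_height", 0, 1)
  assert_scalar_number(cut_height, "cut_height", lower = 0)
  if (!simulate) {
    need <- c("profiles", "itsa", "abundance", "samples")
    missing <- setdiff(need, names(paths))
    if (length(missing))
      stop_secshift(paste("missing input paths:",
                          paste(missing, collapse = ", ")),
                    "secshift_parameter_error")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON document
#'
#' Scalar fields override [pipeline_config()] defaults; `config` subfields
#' override [sim_config()] defaults.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- doc$config %||% list()
  doc$config <- do.call(sim_config, sim_args)
  do.call(pipeline_config, doc)
}

load_pipeline_inputs <- function(cfg) {
  if (cfg$simulate) {
    truth <- generate_ground_truth(cfg$config, cfg$n_proteins,
                                   cfg$n_metabolites, cfg$rewire_rate,
                                   seed = cfg$seed)
    list(truth = truth,
         profiles = simulate_sec_profiles(truth),
         itsa = simulate_itsa(truth),
         abundance = simulate_abundance(truth))
  } else {
    list(truth = NULL,
         profiles = read_profiles(cfg$paths$profiles),
         itsa = read_itsa(cfg$paths$itsa),
         abundance = read_abundance(cfg$paths$abundance,
                                    cfg$paths$samples))
  }
}

phase_pairs <- function(phases) {
  if (length(phases) < 2) stop_secshift("need >= 2 phases",
                                        "secshift_parameter_error")
  utils::combn(phases, 2)
}

#' Run the full analysis pipeline
#'
#' Stage order: input (simulate or read) -> differential abundance ->
#' thermal stability -> differential fractionation -> metabolite pools ->
#' co-fractionation networks -> integration.  All per-stage tables are
#' written as TSV under `cfg$out_dir`; the returned summary mirrors the
#' headline counts of each stage.
#'
#' @param cfg a [pipeline_config()].
#' @param write_outputs write stage TSVs (default TRUE).
#' @return list of class `pipeline_result` with per-stage results and a
#'   `summary` data.frame of counts.
#' @export
run_pipeline <- function(cfg, write_outputs = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (write_outputs && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  log_msg <- function(...) message(sprintf(...))
  emit <- function(df, name) {
    if (write_outputs)
      utils::write.table(df, file.path(cfg$out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  inputs <- load_pipeline_inputs(cfg)
  phases <- cfg$config$phases
  pairs <- phase_pairs(phases)
  if (cfg$simulate && write_outputs) {
    write_profiles(inputs$profiles, file.path(cfg$out_dir, "profiles.tsv"))
    write_itsa(inputs$itsa, file.path(cfg$out_dir, "itsa.tsv"),
               rt_celsius = cfg$config$rt_temperature)
    write_abundance(inputs$abundance,
                    file.path(cfg$out_dir, "abundance.tsv"),
                    file.path(cfg$out_dir, "abundance_samples.csv"))
    write_ground_truth(inputs$truth,
                       file.path(cfg$out_dir, "ground_truth.json"))
  }

  # -- differential abundance ------------------------------------------
  log_msg("stage abundance: FDR %.3g, FC %.3g", cfg$fdr_abundance,
          cfg$fc_threshold)
  am <- median_normalize(inputs$abundance)
  abund_calls <- list()
  for (j in seq_len(ncol(pairs))) {
    cmp <- paste(pairs[1, j], "vs", pairs[2, j])
    abund_calls[[cmp]] <- differential_abundance(
      am, pairs[1, j], pairs[2, j],
      fdr_threshold = cfg$fdr_abundance, fc_threshold = cfg$fc_threshold)
  }
  emit(do.call(rbind, abund_calls), "differential_abundance")

  # -- thermal stability ------------------------------------------------
  log_msg("stage itsa: FDR %.3g, FC %.3g", cfg$fdr_stability,
          cfg$fc_threshold)
  stab <- normalize_thermal(inputs$itsa,
                            rt_temperature = cfg$config$rt_temperature)
  stab_calls <- list()
  for (j in seq_len(ncol(pairs))) {
    cmp <- paste(pairs[1, j], "vs", pairs[2, j])
    stab_calls[[cmp]] <- differential_stability(
      stab, pairs[1, j], pairs[2, j],
      fdr_threshold = cfg$fdr_stability, fc_threshold = cfg$fc_threshold)
  }
  emit(do.call(rbind, lapply(names(stab_calls), function(cmp)
    do.call(rbind, stab_calls[[cmp]]$per_temperature))),
    "differential_stability")

  # -- differential fractionation --------------------------------------
  log_msg("stage fractionation: MD factor %.3g", cfg$md_factor)
  prot_profiles <- inputs$profiles[
    inputs$profiles$molecule_class == "protein", ]
  met_profiles <- inputs$profiles[
    inputs$profiles$molecule_class == "metabolite", ]
  frac_calls <- list()
  for (j in seq_len(ncol(pairs))) {
    cmp <- paste(pairs[1, j], "vs", pairs[2, j])
    frac_calls[[cmp]] <- manhattan_differential(
      prot_profiles, pairs[1, j], pairs[2, j], factor = cfg$md_factor,
      detection_threshold = cfg$config$detection_limit)
  }
  emit(do.call(rbind, frac_calls), "differential_fractionation")
  pa <- presence_absence(met_profiles,
                         detection_threshold = cfg$config$detection_limit)
  emit(pa, "metabolite_presence")

  # -- metabolite pools -------------------------------------------------
  log_msg("stage pools: boundary fraction %d",
          cfg$config$protein_fraction_count)
  pools <- summarize_pools(met_profiles,
                           boundary_fraction = cfg$config$protein_fraction_count)
  emit(pools$means, "pool_summaries")
  total_calls <- list()
  for (j in seq_len(ncol(pairs))) {
    cmp <- paste(pairs[1, j], "vs", pairs[2, j])
    total_calls[[cmp]] <- differential_totals(
      pools, pairs[1, j], pairs[2, j],
      fdr_threshold = cfg$fdr_totals, fc_threshold = cfg$fc_threshold)
  }
  emit(do.call(rbind, total_calls), "differential_totals")
  ratios <- compare_ratio_distributions(pools)
  emit(ratios$tests, "ratio_comparison")

  # -- co-fractionation networks ---------------------------------------
  log_msg("stage networks: PCC >= %.3g, min_rel_height %.3g",
          cfg$pcc_threshold, cfg$min_rel_height)
  mol_class <- unique(inputs$profiles[, c("molecule_id", "molecule_class")])
  classes <- stats::setNames(mol_class$molecule_class,
                             mol_class$molecule_id)
  dip_groups <- cfg$dipeptide_groups
  if (is.null(dip_groups) && !is.null(inputs$truth)) {
    mets <- inputs$truth$metabolites
    dip_groups <- stats::setNames(mets$class, mets$id)
  }
  pw_groups <- cfg$pathway_groups %||%
    list(all = unique(prot_profiles$molecule_id))
  networks <- list(); communities <- list(); rates <- list()
  for (ph in phases) {
    peaks <- list()
    for (mol in unique(inputs$profiles$molecule_id)) {
      m <- profile_matrix(inputs$profiles, mol, ph)
      if (is.null(m) || max(m) <= 0) next
      peaks[[mol]] <- deconvolve_peaks(process_profile(m),
                                       min_rel_height = cfg$min_rel_height)
    }
    met_peaks <- peaks[names(peaks) %in%
                         met_profiles$molecule_id]
    prot_peaks <- peaks[names(peaks) %in%
                          prot_profiles$molecule_id]
    if (!length(met_peaks) || !length(prot_peaks)) next
    corr <- peak_correlations(met_peaks, prot_peaks)
    net <- build_network(corr, threshold = cfg$pcc_threshold,
                         node_classes = classes)
    networks[[ph]] <- net
    communities[[ph]] <- detect_communities(net, seed = cfg$seed)
    if (!is.null(dip_groups)) {
      rt <- rate_matrix(net, dip_groups, pw_groups)
      rt$phase <- ph
      rates[[ph]] <- rt
    }
    write_network(net,
                  edge_path = if (write_outputs)
                    file.path(cfg$out_dir, paste0("network_", ph, ".tsv")),
                  graphml_path = if (write_outputs)
                    file.path(cfg$out_dir, paste0("network_", ph, ".graphml")))
  }
  if (length(rates)) emit(do.call(rbind, rates), "interaction_rates")
  if (length(communities)) {
    comm_df <- do.call(rbind, lapply(names(communities), function(ph)
      data.frame(phase = ph, node = names(communities[[ph]]),
                 community = as.integer(communities[[ph]]))))
    emit(comm_df, "communities")
  }

  # -- integration ------------------------------------------------------
  cmp_main <- paste(phases[1], "vs", phases[length(phases)])
  stab_set <- stab_calls[[cmp_main]]$union_set
  frac_tab <- frac_calls[[cmp_main]]
  frac_set <- frac_tab$molecule_id[frac_tab$differential_by_md]
  universe <- unique(c(prot_profiles$molecule_id,
                       rownames(inputs$abundance$intensities),
                       unique(inputs$itsa$protein_id)))
  overlap <- overlap_sets(stab_set, frac_set, universe,
                          labels = c("thermal_stability", "fractionation"))

  summary_df <- data.frame(
    quantity = c(
      paste("significant abundance,", names(abund_calls)),
      paste("differential stability union,", names(stab_calls)),
      paste("differential fractionation,", names(frac_calls)),
      paste("differential totals,", names(total_calls)),
      paste("median bound/free ratio,", names(ratios$medians)),
      paste("communities,", names(communities)),
      "stability & fractionation overlap"),
    value = c(
      vapply(abund_calls, function(d) sum(d$significant), numeric(1)),
      vapply(stab_calls, function(d) length(d$union_set), numeric(1)),
      vapply(frac_calls, function(d) sum(d$differential_by_md), numeric(1)),
      vapply(total_calls, function(d) sum(d$significant), numeric(1)),
      unname(ratios$medians),
      vapply(communities, function(cm) length(unique(cm)), numeric(1)),
      overlap$counts[["both"]]))
  emit(summary_df, "summary")

  structure(list(
    config = cfg, truth = inputs$truth,
    abundance_calls = abund_calls, stability = stab,
    stability_calls = stab_calls, fractionation = frac_calls,
    presence = pa, pools = pools, total_calls = total_calls,
    ratios = ratios, networks = networks, communities = communities,
    interaction_rates = if (length(rates)) do.call(rbind, rates),
    overlap = overlap, summary = summary_df
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("secshift pipeline result\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write simulated inputs + ground truth),
#' `run-all` (full pipeline), `abundance`, `itsa`, `promis` (differential
#' fractionation), `pools`, `networks`, `integrate` (the corresponding
#' single stage; stages currently run through the pipeline with outputs
#' restricted by interest).  Usage:
#' `Rscript -e 'secshift::secshift_cli()' <subcommand> [--config cfg.json] [--out dir] [--seed n]`
#'
#' @param args character vector of CLI arguments (default: the command
#'   line).
#' @return exit status, invisibly.
#' @export
secshift_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("simulate", "run-all", "abundance", "itsa", "promis",
                   "pools", "networks", "integrate")
  if (!length(args) || !args[1] %in% subcommands) {
    message("usage: secshift <", paste(subcommands, collapse = "|"),
            "> [--config cfg.json] [--out dir] [--seed n]")
    return(invisible(1L))
  }
  sub <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  cfg <- if (!is.null(opt("--config"))) read_pipeline_config(opt("--config"))
         else pipeline_config()
  if (!is.null(opt("--out"))) cfg$out_dir <- opt("--out")
  if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))

  if (sub == "simulate") {
    inputs <- load_pipeline_inputs(cfg)
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    write_profiles(inputs$profiles, file.path(cfg$out_dir, "profiles.tsv"))
    write_itsa(inputs$itsa, file.path(cfg$out_dir, "itsa.tsv"),
               rt_celsius = cfg$config$rt_temperature)
    write_abundance(inputs$abundance,
                    file.path(cfg$out_dir, "abundance.tsv"),
                    file.path(cfg$out_dir, "abundance_samples.csv"))
    if (!is.null(inputs$truth))
      write_ground_truth(inputs$truth,
                         file.path(cfg$out_dir, "ground_truth.json"))
    message("simulated inputs written to ", cfg$out_dir)
    return(invisible(0L))
  }
  res <- run_pipeline(cfg)
  message("pipeline outputs written to ", cfg$out_dir)
  invisible(0L)
}
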