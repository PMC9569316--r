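# Ground-truth generation for the synthetic CF-MS / iTSA world.
#
# The generator programs, per protein: abundance per phase, one or more
# oligomeric states per phase (assembly mass + mixing fraction) and a
# sigmoidal melting midpoint per phase.  A configurable fraction of proteins
# is "rewired" between the first and last phase, either in fractionation
# (complex disassembly into the monomer) or in thermal stability (a +4 C
# melting-midpoint shift).  Metabolites carry a class tag, a total amount
# per phase, an optional protein partner, and a per-phase bound fraction.

#' Generate a simulated ground truth for CF-MS and iTSA data
#'
#' @param config a [sim_config()].
#' @param n_proteins,n_metabolites numbers of molecules to program.
#' @param rewire_rate probability that a protein is programmed as rewired
#'   (independently for fractionation and thermal stability) between the
#'   first and last phase of `config$phases`.
#' @param seed integer seed; identical seeds give identical truths.
#'
#' @return object of class `ground_truth` with elements `proteins`
#'   (data.frame id/length_aa plus per-phase abundance), `states` (nested
#'   list: protein -> phase -> data.frame(mass_kDa, mixing)), `metabolites`
#'   (data.frame with class tag, per-phase total and bound fraction,
#'   partner), `melt` (data.frame protein/phase/midpoint_C/slope),
#'   `rewired_fractionation` and `rewired_stability` (character vectors),
#'   `seed` and `config`.
#' @export
generate_ground_truth <- function(config, n_proteins, n_metabolites,
                                  rewire_rate = 0.2, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n_proteins <- assert_count(n_proteins, "n_proteins", 1L)
  n_metabolites <- assert_count(n_metabolites, "n_metabolites", 1L)
  assert_scalar_number(rewire_rate, "rewire_rate", lower = 0, upper = 1)
  seed <- assert_count(seed, "seed", lower = 0L)

  set.seed(seed)
  phases <- config$phases
  n_phases <- length(phases)
  first_phase <- phases[1L]
  last_phase <- phases[n_phases]

  prot_ids <- sprintf("prot_%04d", seq_len(n_proteins))
  lengths_aa <- sample(100:1500, n_proteins, replace = TRUE)
  monomer_kDa <- lengths_aa * 0.11  # ~110 Da per residue

  # per-phase abundance (arbitrary MS intensity units)
  abundance <- matrix(stats::rlnorm(n_proteins * n_phases,
                                    meanlog = log(1e6), sdlog = 1),
                      nrow = n_proteins, dimnames = list(prot_ids, phases))

  # base oligomeric assembly: monomer multiplied by 2..32, clamped to the
  # calibrated separation range
  mult <- sample(c(2, 4, 8, 16, 32), n_proteins, replace = TRUE)
  assembly_kDa <- pmin(monomer_kDa * mult, 5000)

  rewired_frac <- prot_ids[stats::runif(n_proteins) < rewire_rate]
  rewired_stab <- prot_ids[stats::runif(n_proteins) < rewire_rate]

  # two-state mixing for a subset of proteins, stable across phases unless
  # the protein is fractionation-rewired (then: monomer-only in last phase)
  two_state <- stats::runif(n_proteins) < 0.3
  mix_main <- stats::runif(n_proteins, 0.6, 0.9)
  states <- vector("list", n_proteins)
  names(states) <- prot_ids
  for (i in seq_len(n_proteins)) {
    base <- if (two_state[i]) {
      data.frame(mass_kDa = c(assembly_kDa[i], monomer_kDa[i]),
                 mixing = c(mix_main[i], 1 - mix_main[i]))
    } else {
      data.frame(mass_kDa = assembly_kDa[i], mixing = 1)
    }
    per_phase <- rep(list(base), n_phases)
    names(per_phase) <- phases
    if (prot_ids[i] %in% rewired_frac) {
      per_phase[[last_phase]] <-
        data.frame(mass_kDa = monomer_kDa[i], mixing = 1)
    }
    states[[i]] <- per_phase
  }

  # melting behaviour: midpoint ~ N(52, 2) truncated to the assayed window;
  # stability-rewired proteins gain +4 C in the last phase
  mid_base <- pmin(pmax(stats::rnorm(n_proteins, 52, 2), 46), 58)
  melt_slope <- stats::runif(n_proteins, 0.8, 1.5)
  melt <- do.call(rbind, lapply(seq_along(phases), function(k) {
    mid <- mid_base
    if (phases[k] == last_phase)
      mid[prot_ids %in% rewired_stab] <-
        mid[prot_ids %in% rewired_stab] + 4
    data.frame(protein_id = prot_ids, phase = phases[k],
               midpoint_C = mid, slope = melt_slope)
  }))

  met_ids <- sprintf("met_%04d", seq_len(n_metabolites))
  met_class <- sample(c("dipeptide", "nucleotide", "other"), n_metabolites,
                      replace = TRUE, prob = c(0.5, 0.25, 0.25))
  has_partner <- stats::runif(n_metabolites) < 0.7
  partner <- ifelse(has_partner,
                    sample(prot_ids, n_metabolites, replace = TRUE),
                    NA_character_)
  totals <- matrix(stats::rlnorm(n_metabolites * n_phases,
                                 meanlog = log(1e5), sdlog = 1),
                   nrow = n_metabolites, dimnames = list(met_ids, phases))

  # bound/free odds per phase: low in the fermentative and respiratory
  # phases, markedly higher in early stationary (global binding increase)
  odds_center <- stats::setNames(rep(0.02, n_phases), phases)
  if (n_phases >= 2) odds_center[2] <- 0.026
  if (n_phases >= 3) odds_center[n_phases] <- 0.147
  bound_fraction <- matrix(0, n_metabolites, n_phases,
                           dimnames = list(met_ids, phases))
  for (k in seq_len(n_phases)) {
    odds <- stats::rlnorm(n_metabolites, meanlog = log(odds_center[k]),
                          sdlog = 0.8)
    bound_fraction[, k] <- ifelse(has_partner, odds / (1 + odds), 0)
  }

  truth <- structure(list(
    proteins = data.frame(id = prot_ids, length_aa = lengths_aa,
                          monomer_kDa = monomer_kDa,
                          stringsAsFactors = FALSE),
    abundance = abundance,
    states = states,
    metabolites = data.frame(id = met_ids, class = met_class,
                             partner = partner, stringsAsFactors = FALSE),
    totals = totals,
    bound_fraction = bound_fraction,
    melt = melt,
    rewired_fractionation = rewired_frac,
    rewired_stability = rewired_stab,
    seed = seed,
    config = config
  ), class = "ground_truth")
  validate_ground_truth(truth)
  truth
}

validate_ground_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  for (pid in names(truth$states))
    for (st in truth$states[[pid]])
      if (abs(sum(st$mixing) - 1) > 1e-9)
        stop_secshift(sprintf("mixing fractions of %s do not sum to 1", pid),
                      "secshift_consistency_error")
  if (any(truth$bound_fraction < 0 | truth$bound_fraction > 1))
    stop_secshift("bound_fraction outside [0, 1]",
                  "secshift_consistency_error")
  if (any(truth$totals <= 0) || any(truth$abundance <= 0))
    stop_secshift("amounts must be positive", "secshift_consistency_error")
  bad <- setdiff(c(truth$rewired_fractionation, truth$rewired_stability),
                 truth$proteins$id)
  if (length(bad))
    stop_secshift("rewired sets contain unknown protein ids",
                  "secshift_consistency_error")
  partners <- truth$metabolites$partner
  missing <- setdiff(partners[!is.na(partners)], truth$proteins$id)
  if (length(missing))
    stop_secshift("metabolite partner ids missing from protein list",
                  "secshift_consistency_error")
  invisible(truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", nrow(x$proteins), "proteins,",
      nrow(x$metabolites), "metabolites;",
      length(x$rewired_fractionation), "fractionation-rewired,",
      length(x$rewired_stability), "stability-rewired (seed",
      x$seed, ")\n")
  invisible(x)
}

#' Serialize a ground truth to a JSON sidecar
#'
#' @param truth a `ground_truth`.
#' @param path output file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(
    seed = truth$seed,
    proteins = truth$proteins,
    abundance = as.data.frame(truth$abundance),
    states = lapply(truth$states, function(ph) lapply(ph, as.list)),
    metabolites = truth$metabolites,
    totals = as.data.frame(truth$totals),
    bound_fraction = as.data.frame(truth$bound_fraction),
    melt = truth$melt,
    rewired_fractionation = truth$rewired_fractionation,
    rewired_stability = truth$rewired_stability
  )
  jsonlite::write_json(obj, path, digits = NA, na = "null")
  invisible(path)
}
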