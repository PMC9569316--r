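# Forward simulation of SEC elution profiles, iTSA intensities and bulk
# abundance tables from a programmed ground truth.

# Gaussian band over a fraction window, normalized to unit sum so programmed
# amounts are conserved exactly at zero noise.
unit_gaussian <- function(fractions, center, width) {
  g <- stats::dnorm(fractions, mean = center, sd = width)
  s <- sum(g)
  if (s <= 0) {  # center far outside the window: park all mass at the edge
    g <- as.numeric(fractions == fractions[which.min(abs(fractions - center))])
    s <- sum(g)
  }
  g / s
}

# multiplicative log-normal noise; sigma = 0 returns exactly 1
lnoise <- function(n, sigma) {
  if (sigma == 0) rep(1, n) else stats::rlnorm(n, meanlog = 0, sdlog = sigma)
}

protein_kernel <- function(states, config) {
  prot_fr <- seq_len(config$protein_fraction_count)
  k <- numeric(config$protein_fraction_count)
  for (j in seq_len(nrow(states))) {
    center <- mass_to_fraction(config, states$mass_kDa[j])
    k <- k + states$mixing[j] *
      unit_gaussian(prot_fr, center, config$peak_width_fractions)
  }
  k
}

#' Simulate SEC co-fractionation elution profiles
#'
#' Each protein elutes as a mixture of Gaussian bands, one per programmed
#' oligomeric state, centred at the fraction implied by the molecular-weight
#' calibration, confined to the protein-containing fractions.  A metabolite's
#' bound pool co-elutes under its partner protein's bands; its free pool
#' forms a Gaussian band in the low molecular weight region.  Noise is
#' multiplicative log-normal per (molecule, fraction, replicate); values at
#' or below the detection limit are censored to zero.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param config a [sim_config()]; defaults to the config stored in `truth`.
#' @param seed integer seed (default derived from the truth's seed).
#' @return long-format data.frame of class `elution_profiles` with columns
#'   molecule_id, molecule_class, phase, replicate, fraction, intensity.
#' @export
simulate_sec_profiles <- function(truth, config = truth$config,
                                  seed = derive_seed(truth$seed, 1L)) {
  validate_ground_truth(truth)
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)

  n_fr <- config$n_fractions
  p_fr <- config$protein_fraction_count
  free_idx <- seq.int(p_fr + 1L, n_fr)
  free_center <- p_fr + (n_fr - p_fr) / 2
  free_kernel_full <- c(numeric(p_fr),
                        unit_gaussian(free_idx, free_center,
                                      config$free_peak_width))

  out <- vector("list", 0L)
  for (phase in config$phases) {
    # proteins
    prot_rep <- config$replicates$protein_profile
    for (i in seq_len(nrow(truth$proteins))) {
      pid <- truth$proteins$id[i]
      base <- c(protein_kernel(truth$states[[pid]][[phase]], config),
                numeric(n_fr - p_fr)) * truth$abundance[pid, phase]
      for (r in seq_len(prot_rep)) {
        inten <- base * lnoise(n_fr, config$noise_sigma)
        if (config$detection_limit > 0)
          inten[inten <= config$detection_limit] <- 0
        out[[length(out) + 1L]] <- data.frame(
          molecule_id = pid, molecule_class = "protein", phase = phase,
          replicate = r, fraction = seq_len(n_fr), intensity = inten,
          stringsAsFactors = FALSE)
      }
    }
    # metabolites
    met_rep <- config$replicates$metabolite
    for (i in seq_len(nrow(truth$metabolites))) {
      mid <- truth$metabolites$id[i]
      partner <- truth$metabolites$partner[i]
      bf <- truth$bound_fraction[mid, phase]
      total <- truth$totals[mid, phase]
      if (bf > 0 && is.na(partner))
        stop_secshift(sprintf("metabolite %s bound but has no partner", mid),
                      "secshift_consistency_error")
      bound_kernel <- if (!is.na(partner)) {
        c(protein_kernel(truth$states[[partner]][[phase]], config),
          numeric(n_fr - p_fr))
      } else numeric(n_fr)
      base <- total * (bf * bound_kernel + (1 - bf) * free_kernel_full)
      for (r in seq_len(met_rep)) {
        inten <- base * lnoise(n_fr, config$noise_sigma)
        if (config$detection_limit > 0)
          inten[inten <= config$detection_limit] <- 0
        out[[length(out) + 1L]] <- data.frame(
          molecule_id = mid, molecule_class = "metabolite", phase = phase,
          replicate = r, fraction = seq_len(n_fr), intensity = inten,
          stringsAsFactors = FALSE)
      }
    }
  }
  profiles <- do.call(rbind, out)
  rownames(profiles) <- NULL
  class(profiles) <- c("elution_profiles", "data.frame")
  profiles
}

# soluble-fraction sigmoid; equals 0.5 at the melting midpoint
melt_sigmoid <- function(temperature, midpoint, slope) {
  1 / (1 + exp(slope * (temperature - midpoint)))
}

#' Simulate isothermal shift assay (iTSA) intensities
#'
#' Soluble intensity at an elevated temperature T is
#' `abundance * sigmoid(T; midpoint, slope) * noise`; the room-temperature
#' (RT) intensity is `abundance * noise` (no thermal loss).
#'
#' @inheritParams simulate_sec_profiles
#' @return data.frame of class `itsa_records` with columns protein_id,
#'   phase, temperature (numeric, RT encoded as the lowest temperature),
#'   replicate, intensity.
#' @export
simulate_itsa <- function(truth, config = truth$config,
                          seed = derive_seed(truth$seed, 2L)) {
  validate_ground_truth(truth)
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)

  rt <- config$rt_temperature
  temps <- config$temperatures_C
  reps <- config$replicates$itsa
  melt <- truth$melt
  key <- paste(melt$protein_id, melt$phase)
  rows <- expand.grid(protein_id = truth$proteins$id,
                      phase = config$phases, temperature = temps,
                      replicate = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # deterministic row order so the RNG stream is reproducible
  rows <- rows[order(rows$phase, rows$temperature, rows$replicate,
                     rows$protein_id), , drop = FALSE]
  idx <- match(paste(rows$protein_id, rows$phase), key)
  ab <- truth$abundance[cbind(rows$protein_id, rows$phase)]
  frac_soluble <- ifelse(rows$temperature == rt, 1,
                         melt_sigmoid(rows$temperature,
                                      melt$midpoint_C[idx], melt$slope[idx]))
  rows$intensity <- ab * frac_soluble * lnoise(nrow(rows), config$noise_sigma)
  rownames(rows) <- NULL
  class(rows) <- c("itsa_records", "data.frame")
  rows
}

#' Simulate a bulk protein abundance table
#'
#' Replicated whole-lysate protein intensities per growth phase, i.e. the
#' input to the differential-abundance stage.
#'
#' @inheritParams simulate_sec_profiles
#' @return an `abundance_matrix`: list with `intensities` (proteins x
#'   samples) and `samples` (data.frame sample_id, phase, replicate).
#' @export
simulate_abundance <- function(truth, config = truth$config,
                               seed = derive_seed(truth$seed, 3L)) {
  validate_ground_truth(truth)
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  reps <- config$replicates$abundance
  samples <- expand.grid(replicate = seq_len(reps), phase = config$phases,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("phase", "replicate")]
  samples$sample_id <- paste(samples$phase, samples$replicate, sep = "_r")
  n_p <- nrow(truth$proteins)
  m <- matrix(0, n_p, nrow(samples),
              dimnames = list(truth$proteins$id, samples$sample_id))
  for (j in seq_len(nrow(samples)))
    m[, j] <- truth$abundance[, samples$phase[j]] *
      lnoise(n_p, config$noise_sigma)
  abundance_matrix(m, samples)
}
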