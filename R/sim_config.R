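#' Simulation and pipeline geometry configuration
#'
#' Describes the geometry of a co-fractionation / iTSA experiment: number of
#' SEC fractions, the protein-containing region, growth phase labels,
#' temperature conditions, replicate structure, noise level and the
#' fraction-to-mass calibration. Defaults mirror a 60-fraction SEC separation
#' of which the first 40 fractions contain protein (roughly 5 MDa down to
#' 20 kDa), sampled in three growth phases of a yeast diauxic-shift culture,
#' with iTSA at room temperature plus 48, 52 and 56 degrees C.
#'
#' @param n_fractions total number of SEC fractions (default 60).
#' @param protein_fraction_count number of protein-containing (high
#'   molecular weight) fractions at the start of the gradient (default 40);
#'   fractions beyond this index hold the free, unbound small-molecule pool.
#' @param phases ordered character vector of growth-phase labels.
#' @param temperatures_C numeric vector of iTSA temperatures in degrees C.
#'   Room temperature is encoded internally as 22 and rendered as "RT" in
#'   files; it must be the first element.
#' @param replicates named list with elements `metabolite`,
#'   `protein_profile`, `itsa`, `abundance` giving replicate counts.
#' @param noise_sigma standard deviation (log scale) of the multiplicative
#'   log-normal intensity noise.
#' @param peak_width_fractions Gaussian SD, in fraction units, of a single
#'   SEC elution peak.
#' @param free_peak_width Gaussian SD of the free-pool metabolite band in
#'   the low molecular weight region.
#' @param detection_limit intensities at or below this value are censored to
#'   zero (presence/absence logic downstream); default 0, i.e. no censoring.
#' @param mw_calibration list with `intercept` and `slope` of the linear map
#'   from fraction index to log10(mass in kDa); slope must be negative.
#'   Default spans 5000 kDa at fraction 1 to 20 kDa at fraction
#'   `protein_fraction_count`.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_fractions = 60L,
                       protein_fraction_count = 40L,
                       phases = c("glucose", "ethanol", "early_stationary"),
                       temperatures_C = c(22, 48, 52, 56),
                       replicates = list(metabolite = 3L, protein_profile = 1L,
                                         itsa = 5L, abundance = 5L),
                       noise_sigma = 0.1,
                       peak_width_fractions = 1.5,
                       free_peak_width = 2.5,
                       detection_limit = 0,
                       mw_calibration = NULL) {
  n_fractions <- assert_count(n_fractions, "n_fractions", 2L)
  protein_fraction_count <- assert_count(protein_fraction_count,
                                         "protein_fraction_count", 1L)
  if (protein_fraction_count >= n_fractions)
    stop_secshift("`protein_fraction_count` must be < `n_fractions`",
                  "secshift_parameter_error")
  if (!is.character(phases) || length(phases) < 1L || anyDuplicated(phases))
    stop_secshift("`phases` must be distinct labels",
                  "secshift_parameter_error")
  if (!is.numeric(temperatures_C) || length(temperatures_C) < 2L)
    stop_secshift("`temperatures_C` needs RT plus >= 1 elevated temperature",
                  "secshift_parameter_error")
  for (nm in c("metabolite", "protein_profile", "itsa", "abundance"))
    replicates[[nm]] <- assert_count(replicates[[nm]] %||% 1L,
                                     paste0("replicates$", nm), 1L)
  assert_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  assert_scalar_number(peak_width_fractions, "peak_width_fractions",
                       lower = 1e-6)
  assert_scalar_number(free_peak_width, "free_peak_width", lower = 1e-6)
  assert_scalar_number(detection_limit, "detection_limit", lower = 0)

  if (is.null(mw_calibration)) {
    # 5 MDa at the first fraction down to 20 kDa at the last protein fraction
    slope <- (log10(20) - log10(5000)) / (protein_fraction_count - 1)
    mw_calibration <- list(intercept = log10(5000) - slope, slope = slope)
  }
  if (!is.numeric(mw_calibration$slope) || mw_calibration$slope >= 0)
    stop_secshift("mw_calibration$slope must be negative (earlier = larger)",
                  "secshift_parameter_error")

  structure(list(
    n_fractions = n_fractions,
    protein_fraction_count = protein_fraction_count,
    phases = phases,
    temperatures_C = sort(unique(temperatures_C)),
    rt_temperature = min(temperatures_C),
    replicates = replicates,
    noise_sigma = noise_sigma,
    peak_width_fractions = peak_width_fractions,
    free_peak_width = free_peak_width,
    detection_limit = detection_limit,
    mw_calibration = mw_calibration
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_fractions, "fractions (",
      x$protein_fraction_count, "protein-containing ),",
      length(x$phases), "phases, noise_sigma =", x$noise_sigma, "\n")
  invisible(x)
}

# fraction index implied by a mass under the config's calibration
mass_to_fraction <- function(config, mass_kDa) {
  (log10(mass_kDa) - config$mw_calibration$intercept) /
    config$mw_calibration$slope
}
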