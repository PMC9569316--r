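# Isothermal shift assay processing: soluble-fraction intensities after a
# single-temperature heat challenge are median-normalized within each
# temperature group and scaled to the room-temperature (RT) abundance of
# the same protein/phase/replicate.  Differential thermal stability between
# growth phases is then called per temperature with the same t-test/FDR
# machinery used for abundance, and reported as the union across
# temperatures.

validate_itsa_records <- function(records) {
  need <- c("protein_id", "phase", "temperature", "replicate", "intensity")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_secshift(paste("iTSA records need columns:",
                        paste(need, collapse = ", ")),
                  "secshift_parameter_error")
  if (any(records$intensity < 0, na.rm = TRUE))
    stop_secshift("iTSA intensities must be nonnegative",
                  "secshift_parameter_error")
  invisible(records)
}

#' Normalize iTSA intensities to thermal-stability values
#'
#' Within each temperature group, samples (phase x replicate columns) are
#' median-equalized exactly as in [median_normalize()]; the stability of a
#' protein at temperature T is its normalized intensity divided by its
#' normalized RT intensity in the same phase and replicate.  RT stability
#' is therefore identically 1.
#'
#' @param records long data.frame (protein_id, phase, temperature,
#'   replicate, intensity); the lowest temperature is taken as RT unless
#'   `rt_temperature` is given.
#' @param rt_temperature numeric RT encoding (default: minimum observed).
#' @return data.frame of class `stability_values` with columns protein_id,
#'   phase, temperature, replicate, stability.  Proteins with zero or
#'   missing RT intensity get NA stability and are flagged in the
#'   `unscalable` attribute.
#' @export
normalize_thermal <- function(records, rt_temperature = NULL) {
  validate_itsa_records(records)
  rt <- rt_temperature %||% min(records$temperature)
  if (!any(records$temperature == rt))
    stop_secshift("no RT measurements found", "secshift_parameter_error")

  # median-equalize within each temperature group
  records$.norm <- NA_real_
  for (tp in unique(records$temperature)) {
    sel <- records$temperature == tp
    sub <- records[sel, ]
    sid <- paste(sub$phase, sub$replicate)
    med <- tapply(sub$intensity, sid, function(v) {
      v <- v[is.finite(v) & v > 0]
      if (!length(v)) 0 else stats::median(v)
    })
    if (any(med <= 0))
      stop_secshift(sprintf("zero sample median in temperature group %s", tp),
                    "secshift_normalization_error")
    global <- stats::median(med)
    records$.norm[sel] <- sub$intensity * (global / med[sid])
  }

  rt_rows <- records[records$temperature == rt, ]
  rt_key <- paste(rt_rows$protein_id, rt_rows$phase, rt_rows$replicate)
  key <- paste(records$protein_id, records$phase, records$replicate)
  rt_norm <- rt_rows$.norm[match(key, rt_key)]
  stability <- ifelse(is.na(rt_norm) | rt_norm <= 0, NA_real_,
                      records$.norm / rt_norm)
  out <- data.frame(protein_id = records$protein_id, phase = records$phase,
                    temperature = records$temperature,
                    replicate = records$replicate,
                    stability = stability, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  unscalable <- unique(out$protein_id[is.na(out$stability)])
  structure(out, class = c("stability_values", "data.frame"),
            rt_temperature = rt, unscalable = unscalable)
}

#' Differential thermal stability between two growth phases
#'
#' Runs the differential-testing machinery independently at every elevated
#' temperature on the stability values and reports the per-temperature
#' calls plus their union ("differential thermal stability" set).
#'
#' @param stabilities a [normalize_thermal()] result.
#' @param phaseA,phaseB phase labels to compare.
#' @param fdr_threshold,fc_threshold call thresholds (defaults 0.01 and 2).
#' @param var_equal Student (TRUE, default) or Welch t-test.
#' @return list of class `differential_stability` with `per_temperature`
#'   (named list of `differential_calls`) and `union_set` (character vector
#'   of proteins significant at any temperature).
#' @export
differential_stability <- function(stabilities, phaseA, phaseB,
                                   fdr_threshold = 0.01, fc_threshold = 2,
                                   var_equal = TRUE) {
  stopifnot(inherits(stabilities, "stability_values"))
  rt <- attr(stabilities, "rt_temperature")
  temps <- sort(setdiff(unique(stabilities$temperature), rt))
  per_temp <- list()
  for (tp in temps) {
    sub <- stabilities[stabilities$temperature == tp &
                         stabilities$phase %in% c(phaseA, phaseB), ]
    # features x samples matrix + sample sheet for the shared test machinery
    samp <- unique(sub[, c("phase", "replicate")])
    samp <- samp[order(samp$phase, samp$replicate), ]
    samp$sample_id <- paste(samp$phase, samp$replicate, sep = "_r")
    prot <- sort(unique(sub$protein_id))
    m <- matrix(NA_real_, length(prot), nrow(samp),
                dimnames = list(prot, samp$sample_id))
    idx <- cbind(match(sub$protein_id, prot),
                 match(paste(sub$phase, sub$replicate, sep = "_r"),
                       samp$sample_id))
    m[idx] <- sub$stability
    per_temp[[as.character(tp)]] <- differential_calls(
      m, samp, phaseA, phaseB, fdr_threshold, fc_threshold, var_equal,
      comparison = sprintf("%s vs %s @%sC", phaseA, phaseB, tp))
  }
  union_set <- sort(unique(unlist(lapply(per_temp, function(d)
    d$feature_id[d$significant]))))
  structure(list(per_temperature = per_temp, union_set = union_set),
            class = "differential_stability")
}

#' @export
print.differential_stability <- function(x, ...) {
  for (tp in names(x$per_temperature))
    cat(sprintf("  %s C: %d significant\n", tp,
                sum(x$per_temperature[[tp]]$significant)))
  cat("  union:", length(x$union_set), "proteins\n")
  invisible(x)
}

#' Correlation between protein length and thermal stability
#'
#' Pearson correlation of chain length (amino acids) with the stability
#' value at a chosen temperature, reproducing the classic weak negative
#' length-stability relationship.
#'
#' @param stabilities a `stability_values` data.frame.
#' @param lengths_aa named numeric vector of chain lengths per protein id.
#' @param temperature temperature at which to take stability (default 56).
#' @param phase optional phase filter.
#' @return list with `estimate` (Pearson r) and `p_value`.
#' @export
length_stability_correlation <- function(stabilities, lengths_aa,
                                         temperature = 56, phase = NULL) {
  stopifnot(inherits(stabilities, "stability_values"))
  sub <- stabilities[stabilities$temperature == temperature, ]
  if (!is.null(phase)) sub <- sub[sub$phase %in% phase, ]
  agg <- tapply(sub$stability, sub$protein_id, mean, na.rm = TRUE)
  shared <- intersect(names(agg), names(lengths_aa))
  correlate_scalars(lengths_aa[shared], as.numeric(agg[shared]))
}
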