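# Protein-bound vs free metabolite pool analytics.  The protein-containing
# fractions (1..boundary) hold the bound pool of a metabolite, the trailing
# low molecular weight fractions its free pool; the bound/free ratio tracks
# global changes in metabolite binding across growth phases.

#' Summarize metabolite pools per phase
#'
#' Sums each metabolite's intensity over all fractions (total), the
#' protein-containing fractions (bound, 1..`boundary_fraction`) and the
#' remaining fractions (free); sums are taken per replicate and then
#' averaged.  The bound/free ratio is `bound / free`; when `free` is zero
#' but `bound` positive, the smallest positive free sum in the dataset is
#' used as a pseudo-denominator and the row is flagged.
#'
#' @param profiles an `elution_profiles` data.frame (typically the
#'   metabolite subset).
#' @param boundary_fraction last protein-containing fraction (default 40).
#' @return list of class `pool_summaries` with `per_replicate` and `means`
#'   data.frames (metabolite_id, phase, [replicate,] total, bound, free,
#'   ratio, ratio_flagged).
#' @export
summarize_pools <- function(profiles, boundary_fraction = 40L) {
  validate_profiles(profiles)
  n_fr <- max(profiles$fraction)
  boundary_fraction <- assert_count(boundary_fraction, "boundary_fraction", 1L)
  if (boundary_fraction >= n_fr)
    stop_secshift("boundary_fraction must be below the number of fractions",
                  "secshift_parameter_error")
  bound_flag <- profiles$fraction <= boundary_fraction
  key <- list(profiles$molecule_id, profiles$phase, profiles$replicate)
  total <- tapply(profiles$intensity, key, sum)
  bound <- tapply(profiles$intensity * bound_flag, key, sum)
  idx <- which(!is.na(total), arr.ind = TRUE)
  per_rep <- data.frame(
    metabolite_id = dimnames(total)[[1]][idx[, 1]],
    phase = dimnames(total)[[2]][idx[, 2]],
    replicate = as.integer(dimnames(total)[[3]][idx[, 3]]),
    total = total[idx], bound = bound[idx],
    stringsAsFactors = FALSE)
  per_rep$free <- per_rep$total - per_rep$bound

  agg <- stats::aggregate(cbind(total, bound, free) ~ metabolite_id + phase,
                          data = per_rep, FUN = mean)
  eps <- suppressWarnings(min(agg$free[agg$free > 0]))
  ratio_of <- function(bound, free) {
    flagged <- free <= 0 & bound > 0
    ratio <- ifelse(free > 0, bound / free,
                    ifelse(bound > 0, bound / eps, NA_real_))
    list(ratio = ratio, flagged = flagged)
  }
  rm_ <- ratio_of(agg$bound, agg$free)
  agg$ratio <- rm_$ratio; agg$ratio_flagged <- rm_$flagged
  rp_ <- ratio_of(per_rep$bound, per_rep$free)
  per_rep$ratio <- rp_$ratio; per_rep$ratio_flagged <- rp_$flagged

  structure(list(per_replicate = per_rep, means = agg,
                 boundary_fraction = boundary_fraction,
                 pseudo_free = if (is.finite(eps)) eps else NA_real_),
            class = "pool_summaries")
}

#' Differential total metabolite abundance between phases
#'
#' Applies the differential-testing machinery to per-replicate total
#' abundances (sum over the full fractionation profile).
#'
#' @param pools a [summarize_pools()] result.
#' @param phaseA,phaseB phase labels.
#' @param fdr_threshold,fc_threshold call thresholds (defaults 0.05 and 2).
#' @return a `differential_calls` data.frame.
#' @export
differential_totals <- function(pools, phaseA, phaseB,
                                fdr_threshold = 0.05, fc_threshold = 2) {
  stopifnot(inherits(pools, "pool_summaries"))
  pr <- pools$per_replicate[pools$per_replicate$phase %in%
                              c(phaseA, phaseB), ]
  samp <- unique(pr[, c("phase", "replicate")])
  samp <- samp[order(samp$phase, samp$replicate), ]
  samp$sample_id <- paste(samp$phase, samp$replicate, sep = "_r")
  ids <- sort(unique(pr$metabolite_id))
  m <- matrix(NA_real_, length(ids), nrow(samp),
              dimnames = list(ids, samp$sample_id))
  m[cbind(match(pr$metabolite_id, ids),
          match(paste(pr$phase, pr$replicate, sep = "_r"),
                samp$sample_id))] <- pr$total
  differential_calls(m, samp, phaseA, phaseB, fdr_threshold, fc_threshold)
}

#' Compare bound/free ratio distributions between phases
#'
#' Reports the per-phase median of per-metabolite bound/free ratios and,
#' for every phase pair, a two-sided Wilcoxon signed-rank test on the
#' paired log2 ratios of metabolites shared between the phases.
#'
#' @param pools a [summarize_pools()] result.
#' @return list with `medians` (named by phase) and `tests` (data.frame
#'   phaseA, phaseB, n_paired, p_value).
#' @export
compare_ratio_distributions <- function(pools) {
  stopifnot(inherits(pools, "pool_summaries"))
  mn <- pools$means
  phases <- unique(mn$phase)
  if (any(table(mn$phase) < 3))
    stop_secshift("need >= 3 metabolites per phase",
                  "secshift_parameter_error")
  medians <- vapply(phases, function(ph)
    stats::median(mn$ratio[mn$phase == ph], na.rm = TRUE), numeric(1))
  pairs <- utils::combn(phases, 2)
  tests <- data.frame()
  for (j in seq_len(ncol(pairs))) {
    a <- mn[mn$phase == pairs[1, j], c("metabolite_id", "ratio")]
    b <- mn[mn$phase == pairs[2, j], c("metabolite_id", "ratio")]
    mrg <- merge(a, b, by = "metabolite_id", suffixes = c(".a", ".b"))
    la <- log2(mrg$ratio.a); lb <- log2(mrg$ratio.b)
    ok <- is.finite(la) & is.finite(lb)
    d <- la[ok] - lb[ok]
    p <- if (!length(d) || all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(la[ok], lb[ok], paired = TRUE,
                                          exact = FALSE)$p.value)
    tests <- rbind(tests, data.frame(
      phaseA = pairs[1, j], phaseB = pairs[2, j],
      n_paired = sum(ok), n_dropped = sum(!ok), p_value = p))
  }
  list(medians = medians, tests = tests)
}
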