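# Elution-profile primitives: normalization, replicate aggregation, peak
# deconvolution and SEC molecular-weight calibration.  These operate on
# plain numeric intensity vectors over ordered fractions (1-based, ordered
# by decreasing molecular size); long-format containers are handled by the
# accessor helpers in io.R.

#' Normalize an elution profile to its maximum
#'
#' @param x nonnegative numeric vector of fraction intensities.
#' @return `x / max(x)`; the maximum of the result is exactly 1.
#' @export
normalize_to_max <- function(x) {
  if (!is.numeric(x) || any(x < 0, na.rm = TRUE))
    stop_secshift("profile must be nonnegative numeric",
                  "secshift_parameter_error")
  m <- max(x)
  if (!is.finite(m) || m <= 0)
    stop_secshift("cannot normalize an all-zero profile",
                  "secshift_degenerate_profile")
  x / m
}

#' Aggregate replicate elution profiles by fraction-wise mean
#'
#' @param x numeric matrix with one row per replicate (a vector is treated
#'   as a single replicate and returned unchanged).
#' @return numeric vector of column means.
#' @export
aggregate_replicates <- function(x) {
  if (is.null(dim(x))) return(as.numeric(x))
  if (!is.matrix(x) || nrow(x) < 1L)
    stop_secshift("need a replicate-by-fraction matrix",
                  "secshift_shape_error")
  colMeans(x)
}

# leftmost local maxima, plateau-aware: position i is an apex when it is the
# first point of a run strictly above both flanking values (profile ends
# count as -Inf)
local_maxima <- function(x) {
  n <- length(x)
  if (n == 1L) return(if (x[1] > 0) 1L else integer(0))
  apex <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L  # plateau run [i, j]
    left <- if (i == 1L) -Inf else x[i - 1L]
    right <- if (j == n) -Inf else x[j + 1L]
    if (x[i] > left && x[i] > right && x[i] > 0) apex <- c(apex, i)
    i <- j + 1L
  }
  apex
}

#' Deconvolve an elution profile into single peaks
#'
#' Detects local maxima (leftmost point of a plateau), suppresses maxima
#' closer than `min_separation` fractions to a retained higher maximum,
#' drops maxima below `min_rel_height` of the main maximum, and places peak
#' boundaries at the deepest local minimum between adjacent retained apexes
#' (profile ends otherwise).  Subprofiles partition the retained signal:
#' the inter-peak minimum belongs to the left peak.
#'
#' @param x nonnegative intensity vector with a positive maximum.
#' @param min_rel_height retain maxima at least this fraction of the main
#'   maximum (default 0.10).
#' @param min_separation minimum apex spacing in fractions (default 2);
#'   1 disables the suppression.
#' @param smooth apply a 3-point moving average before maxima detection
#'   (default FALSE: raw profile).
#' @return object of class `peak_set`: list with `peaks` (data.frame
#'   apex_fraction, left_bound, right_bound, height with main peak = 1)
#'   and `subprofiles` (list of vectors, zero outside the peak bounds).
#' @export
deconvolve_peaks <- function(x, min_rel_height = 0.10, min_separation = 2L,
                             smooth = FALSE) {
  if (!is.numeric(x) || any(x < 0))
    stop_secshift("profile must be nonnegative numeric",
                  "secshift_parameter_error")
  if (max(x) <= 0)
    stop_secshift("cannot deconvolve an all-zero profile",
                  "secshift_degenerate_profile")
  assert_scalar_number(min_rel_height, "min_rel_height", 0, 1)
  min_separation <- assert_count(min_separation, "min_separation", 1L)
  n <- length(x)
  y <- x
  if (smooth && n >= 3L) {
    y <- x
    y[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  }
  cand <- local_maxima(y)
  # greedy suppression: keep by decreasing height (ties: leftmost first)
  cand <- cand[order(-y[cand], cand)]
  kept <- integer(0)
  for (a in cand)
    if (!length(kept) || min(abs(kept - a)) >= min_separation)
      kept <- c(kept, a)
  main <- max(y[kept])
  kept <- sort(kept[y[kept] >= min_rel_height * main])

  k <- length(kept)
  left <- integer(k); right <- integer(k)
  left[1] <- 1L; right[k] <- n
  if (k > 1L) {
    for (j in seq_len(k - 1L)) {
      between <- seq.int(kept[j], kept[j + 1L])
      cut <- between[which.min(y[between])]       # deepest inter-apex minimum
      right[j] <- cut
      left[j + 1L] <- cut + 1L
    }
  }
  subprofiles <- lapply(seq_len(k), function(j) {
    s <- numeric(n)
    s[left[j]:right[j]] <- x[left[j]:right[j]]
    s
  })
  structure(list(
    peaks = data.frame(apex_fraction = kept, left_bound = left,
                       right_bound = right, height = y[kept] / main),
    subprofiles = subprofiles,
    n_fractions = n
  ), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set with", nrow(x$peaks), "peak(s); apexes:",
      paste(x$peaks$apex_fraction, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a SEC molecular-weight calibration from reference standards
#'
#' Least-squares line of log10(mass in kDa) on fraction index; the slope
#' must come out negative (earlier fractions elute larger species).
#'
#' @param standards data.frame with columns `fraction` and `mass_kDa`
#'   (>= 2 rows, distinct fractions).
#' @return object of class `mw_calibration` with `intercept`, `slope` and
#'   the standards used.
#' @export
fit_mw_calibration <- function(standards) {
  if (!is.data.frame(standards) ||
      !all(c("fraction", "mass_kDa") %in% names(standards)) ||
      nrow(standards) < 2L)
    stop_secshift("need >= 2 standards with columns fraction, mass_kDa",
                  "secshift_parameter_error")
  if (length(unique(standards$fraction)) < 2L)
    stop_secshift("standards must span >= 2 distinct fractions",
                  "secshift_rank_error")
  if (any(standards$mass_kDa <= 0))
    stop_secshift("standard masses must be positive",
                  "secshift_parameter_error")
  fit <- stats::lm(log10(mass_kDa) ~ fraction, data = standards)
  co <- stats::coef(fit)
  cal <- structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                        standards = standards), class = "mw_calibration")
  if (cal$slope >= 0)
    stop_secshift("fitted slope is nonnegative: standards do not elute by decreasing size",
                  "secshift_rank_error")
  cal
}

#' Map a fraction index to apparent molecular mass
#'
#' @param cal a [fit_mw_calibration()] result or a list with `intercept`
#'   and `slope`.
#' @param fraction numeric fraction index (vectorized).
#' @return mass in kDa; strictly decreasing in `fraction`.
#' @export
fraction_to_mass <- function(cal, fraction) {
  10^(cal$intercept + cal$slope * fraction)
}
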