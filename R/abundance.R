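# Median normalization and pairwise differential testing of protein (or
# metabolite) intensity matrices.  The same vectorized two-sample t-test
# machinery backs differential abundance, differential thermal stability
# and differential metabolite totals.

#' Construct an abundance matrix container
#'
#' @param intensities nonnegative numeric matrix, features x samples.
#' @param samples data.frame with columns `sample_id`, `phase`, `replicate`
#'   describing the columns of `intensities` (in order).
#' @return object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(intensities, samples) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop_secshift("`intensities` must be a numeric matrix",
                  "secshift_parameter_error")
  if (any(intensities < 0, na.rm = TRUE))
    stop_secshift("intensities must be nonnegative",
                  "secshift_parameter_error")
  if (!is.data.frame(samples) ||
      !all(c("phase", "replicate") %in% names(samples)) ||
      nrow(samples) != ncol(intensities))
    stop_secshift("`samples` must describe every column (phase, replicate)",
                  "secshift_parameter_error")
  if (is.null(samples$sample_id))
    samples$sample_id <- paste(samples$phase, samples$replicate, sep = "_r")
  colnames(intensities) <- samples$sample_id
  structure(list(intensities = intensities,
                 samples = samples[, c("sample_id", "phase", "replicate")]),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$intensities), "features x",
      ncol(x$intensities), "samples (",
      paste(unique(x$samples$phase), collapse = ", "), ")\n")
  invisible(x)
}

# medians over positive entries; zeros are treated as missing throughout
sample_medians <- function(m) {
  apply(m, 2, function(col) {
    v <- col[is.finite(col) & col > 0]
    if (!length(v)) return(0)
    stats::median(v)
  })
}

#' Median-normalize an abundance matrix
#'
#' Each sample is rescaled so its median intensity (over positive values)
#' equals the global median, defined as the median of the per-sample
#' medians.  This removes per-sample loading differences while preserving
#' within-sample ratios.
#'
#' @param am an [abundance_matrix()].
#' @return the matrix with normalized intensities.
#' @export
median_normalize <- function(am) {
  stopifnot(inherits(am, "abundance_matrix"))
  med <- sample_medians(am$intensities)
  if (any(med <= 0))
    stop_secshift("every sample needs a positive median intensity",
                  "secshift_normalization_error")
  global <- stats::median(med)
  am$intensities <- sweep(am$intensities, 2, global / med, `*`)
  am
}

# Vectorized two-sample t-test on log2 intensities.  Zeros/NAs are missing;
# rows with < 2 usable values in either group are untestable (p = NA) and
# excluded from the FDR adjustment.
row_t_test <- function(a, b, var_equal = TRUE) {
  la <- log2(ifelse(is.finite(a) & a > 0, a, NA))
  lb <- log2(ifelse(is.finite(b) & b > 0, b, NA))
  na <- rowSums(!is.na(la)); nb <- rowSums(!is.na(lb))
  ma <- rowMeans(la, na.rm = TRUE); mb <- rowMeans(lb, na.rm = TRUE)
  va <- apply(la, 1, stats::var, na.rm = TRUE)
  vb <- apply(lb, 1, stats::var, na.rm = TRUE)
  testable <- na >= 2 & nb >= 2
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!testable | !is.finite(p)] <- NA
  # linear-scale group means for the fold change
  mean_a <- rowMeans(ifelse(is.finite(a) & a > 0, a, NA), na.rm = TRUE)
  mean_b <- rowMeans(ifelse(is.finite(b) & b > 0, b, NA), na.rm = TRUE)
  list(p = p, log2_fc = log2(mean_a / mean_b), testable = testable)
}

# shared caller: builds DifferentialCall records from two sample groups
differential_calls <- function(values, samples, phaseA, phaseB,
                               fdr_threshold, fc_threshold,
                               var_equal = TRUE,
                               comparison = paste(phaseA, "vs", phaseB)) {
  for (ph in c(phaseA, phaseB))
    if (!ph %in% samples$phase)
      stop_secshift(sprintf("phase '%s' not present in the sample sheet", ph),
                    "secshift_parameter_error")
  a <- values[, samples$phase == phaseA, drop = FALSE]
  b <- values[, samples$phase == phaseB, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop_secshift("need >= 2 replicates per phase for testing",
                  "secshift_parameter_error")
  tt <- row_t_test(a, b, var_equal = var_equal)
  q <- rep(NA_real_, length(tt$p))
  q[tt$testable] <- stats::p.adjust(tt$p[tt$testable], method = "BH")
  res <- data.frame(
    feature_id = rownames(values),
    comparison = comparison,
    log2_fc = tt$log2_fc,
    p_value = tt$p,
    q_value = q,
    tested = tt$testable,
    stringsAsFactors = FALSE)
  res$significant <- !is.na(q) & q < fdr_threshold &
    abs(res$log2_fc) > log2(fc_threshold)
  rownames(res) <- NULL
  class(res) <- c("differential_calls", "data.frame")
  res
}

#' Pairwise differential protein abundance
#'
#' Two-sided two-sample t-test (Student by default) on log2 intensities
#' between two growth phases, Benjamini-Hochberg FDR across all testable
#' features, fold change from the ratio of (linear) phase means.  A feature
#' is significant when `q < fdr_threshold` and `|log2 FC| > log2(fc_threshold)`.
#' Zeros are treated as missing; features with fewer than 2 usable
#' replicates in either phase are marked untestable and excluded from the
#' FDR adjustment.
#'
#' @param am an [abundance_matrix()] (normalize first with
#'   [median_normalize()]).
#' @param phaseA,phaseB phase labels to compare (fold change is A over B).
#' @param fdr_threshold FDR cut-off (default 0.01).
#' @param fc_threshold fold-change cut-off on the linear scale (default 2).
#' @param var_equal Student's pooled-variance test when TRUE (default);
#'   Welch when FALSE.
#' @return data.frame of class `differential_calls` with feature_id,
#'   comparison, log2_fc, p_value, q_value, tested, significant.
#' @export
differential_abundance <- function(am, phaseA, phaseB,
                                   fdr_threshold = 0.01, fc_threshold = 2,
                                   var_equal = TRUE) {
  stopifnot(inherits(am, "abundance_matrix"))
  assert_scalar_number(fdr_threshold, "fdr_threshold", 0, 1)
  assert_scalar_number(fc_threshold, "fc_threshold", lower = 1)
  differential_calls(am$intensities, am$samples, phaseA, phaseB,
                     fdr_threshold, fc_threshold, var_equal)
}

#' Volcano-ready table from differential calls
#'
#' @param calls a `differential_calls` data.frame.
#' @return data.frame with feature_id, log2_fc and -log10(p).
#' @export
volcano_table <- function(calls) {
  stopifnot(inherits(calls, "differential_calls"))
  data.frame(feature_id = calls$feature_id, log2_fc = calls$log2_fc,
             neg_log10_p = -log10(calls$p_value),
             significant = calls$significant)
}
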