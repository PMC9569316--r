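# Cross-experiment integration: overlap of thermal-stability and
# fractionation call sets, scalar correlations, and group length
# comparisons.

#' Overlap report for two differential call sets
#'
#' @param set_a,set_b character vectors (e.g. differential-stability and
#'   differential-fractionation protein ids); both must be subsets of
#'   `universe`.
#' @param universe all proteins shared between the experiments.
#' @param labels length-2 character vector naming the sets.
#' @return list of class `overlap_report` with `counts`
#'   (a_only/b_only/both/neither) and `members` (the corresponding id
#'   lists).
#' @export
overlap_sets <- function(set_a, set_b, universe,
                         labels = c("A", "B")) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  out_of <- setdiff(c(set_a, set_b), universe)
  if (length(out_of))
    stop_secshift(sprintf("%d members fall outside the universe (e.g. %s)",
                          length(out_of), out_of[1]),
                  "secshift_validation_error")
  both <- intersect(set_a, set_b)
  a_only <- setdiff(set_a, set_b)
  b_only <- setdiff(set_b, set_a)
  neither <- setdiff(universe, union(set_a, set_b))
  structure(list(
    labels = labels,
    counts = c(a_only = length(a_only), b_only = length(b_only),
               both = length(both), neither = length(neither)),
    members = list(a_only = sort(a_only), b_only = sort(b_only),
                   both = sort(both), neither = sort(neither)),
    universe_size = length(unique(universe))
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap of %s (n=%d) and %s (n=%d) in universe of %d:\n",
              x$labels[1], x$counts[["a_only"]] + x$counts[["both"]],
              x$labels[2], x$counts[["b_only"]] + x$counts[["both"]],
              x$universe_size))
  cat(sprintf("  both %d | %s only %d | %s only %d\n",
              x$counts[["both"]], x$labels[1], x$counts[["a_only"]],
              x$labels[2], x$counts[["b_only"]]))
  invisible(x)
}

#' Pearson correlation between two per-protein scalars
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @return list with `estimate` (Pearson r) and `p_value` (two-sided,
#'   t-distribution); both NA with a message when either input has zero
#'   variance.
#' @export
correlate_scalars <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop_secshift("need >= 3 paired finite values",
                  "secshift_parameter_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(estimate = NA_real_, p_value = NA_real_,
                note = "zero variance"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Compare chain-length distributions between protein groups
#'
#' @param groups named character/factor vector: protein id -> group label.
#' @param lengths_aa named numeric vector of chain lengths (amino acids).
#' @return list with `medians` (per-group median length) and `tests`
#'   (pairwise two-sided Mann-Whitney p-values); empty groups are dropped
#'   and reported in `dropped`.
#' @export
compare_group_lengths <- function(groups, lengths_aa) {
  shared <- intersect(names(groups), names(lengths_aa))
  groups <- groups[shared]
  lens <- lengths_aa[shared]
  tab <- table(groups)
  dropped <- names(tab)[tab == 0]
  keep <- names(tab)[tab > 0]
  if (length(keep) < 2L)
    stop_secshift("need >= 2 nonempty groups", "secshift_parameter_error")
  medians <- vapply(keep, function(g)
    stats::median(lens[groups == g]), numeric(1))
  pairs <- utils::combn(keep, 2)
  tests <- data.frame()
  for (j in seq_len(ncol(pairs))) {
    a <- lens[groups == pairs[1, j]]
    b <- lens[groups == pairs[2, j]]
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    tests <- rbind(tests, data.frame(
      group_a = pairs[1, j], group_b = pairs[2, j],
      n_a = length(a), n_b = length(b), p_value = p,
      stringsAsFactors = FALSE))
  }
  list(medians = medians, tests = tests, dropped = dropped)
}
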