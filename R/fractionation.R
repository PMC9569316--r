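# Differential fractionation: molecules whose SEC elution profiles differ
# between growth phases.  Proteins are called by the Manhattan-distance
# criterion (distance > 1.5x the median distance over all compared
# molecules); replicated molecules (metabolites) additionally get a
# permutation-based dis-elution score surrogate; presence/absence handles
# molecules detected in only one phase.

#' Process an elution profile for comparison
#'
#' Replicate-aggregated, max-normalized, unit-sum intensity vector: the
#' "processed elution profile" on which Manhattan distances and peak
#' deconvolution operate.
#'
#' @param mat_or_vec replicate x fraction matrix or a single profile
#'   vector.
#' @return unit-sum numeric vector.
#' @export
process_profile <- function(mat_or_vec) {
  v <- aggregate_replicates(mat_or_vec)
  v <- normalize_to_max(v)
  v / sum(v)
}

manhattan_distance <- function(a, b) sum(abs(a - b))

#' Differential fractionation by the Manhattan-distance criterion
#'
#' For every molecule present in both phases, the Manhattan distance (MD)
#' is computed between the processed (replicate-aggregated, max-normalized,
#' unit-sum) elution profiles; a molecule is differential when its MD
#' exceeds `factor` times the median MD of all compared molecules in this
#' pairwise comparison.  Molecules detected in only one phase are routed to
#' presence/absence and excluded from the MD median.
#'
#' @param profiles an `elution_profiles` long data.frame (see
#'   [read_profiles()] / [simulate_sec_profiles()]).
#' @param phaseA,phaseB phase labels to compare.
#' @param factor MD threshold multiplier (default 1.5).
#' @param detection_threshold a molecule is present in a phase when its
#'   maximum raw intensity exceeds this value (default 0).
#' @return data.frame of class `profile_comparisons` with molecule_id,
#'   phaseA, phaseB, manhattan_distance, differential_by_md,
#'   present_A/present_B; the MD median used is in attribute `md_median`.
#' @export
manhattan_differential <- function(profiles, phaseA, phaseB, factor = 1.5,
                                   detection_threshold = 0) {
  validate_profiles(profiles)
  assert_scalar_number(factor, "factor", lower = 0)
  assert_scalar_number(detection_threshold, "detection_threshold", lower = 0)
  mols <- unique(profiles$molecule_id)
  res <- data.frame(molecule_id = mols, phaseA = phaseA, phaseB = phaseB,
                    manhattan_distance = NA_real_,
                    differential_by_md = FALSE,
                    present_A = FALSE, present_B = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(mols)) {
    ma <- profile_matrix(profiles, mols[i], phaseA)
    mb <- profile_matrix(profiles, mols[i], phaseB)
    pa <- !is.null(ma) && max(ma) > detection_threshold
    pb <- !is.null(mb) && max(mb) > detection_threshold
    res$present_A[i] <- pa
    res$present_B[i] <- pb
    if (pa && pb)
      res$manhattan_distance[i] <-
        manhattan_distance(process_profile(ma), process_profile(mb))
  }
  md_median <- stats::median(res$manhattan_distance, na.rm = TRUE)
  res$differential_by_md <- !is.na(res$manhattan_distance) &
    res$manhattan_distance > factor * md_median
  structure(res, class = c("profile_comparisons", "data.frame"),
            md_median = md_median, factor = factor)
}

#' Permutation dis-elution score for replicated profiles
#'
#' Surrogate pairwise dis-elution statistic: the score is the Manhattan
#' distance between the processed replicate-mean profiles of the two
#' phases; its p-value is the fraction of replicate-label permutations
#' (group reassignments of the pooled replicates) whose score is at least
#' the observed one, with add-one smoothing.  All distinct splits are
#' enumerated when there are at most `n_permutations` of them; otherwise
#' `n_permutations` random splits are drawn (seeded).
#'
#' @param repsA,repsB replicate x fraction intensity matrices for the two
#'   phases.
#' @param n_permutations permutation budget (default 1000).
#' @param seed RNG seed for sampled permutations.
#' @return list with `score`, `p_value` (NA when either phase has < 2
#'   replicates) and `n_permutations_used`.
#' @export
dis_elution_score <- function(repsA, repsB, n_permutations = 1000L,
                              seed = 1L) {
  if (is.null(dim(repsA))) repsA <- matrix(repsA, nrow = 1)
  if (is.null(dim(repsB))) repsB <- matrix(repsB, nrow = 1)
  if (ncol(repsA) != ncol(repsB))
    stop_secshift("phases must share the fraction grid",
                  "secshift_shape_error")
  n_permutations <- assert_count(n_permutations, "n_permutations", 1L)
  score <- manhattan_distance(process_profile(repsA), process_profile(repsB))
  na <- nrow(repsA); nb <- nrow(repsB)
  if (na < 2L || nb < 2L)
    return(list(score = score, p_value = NA_real_,
                n_permutations_used = 0L))
  pool <- rbind(repsA, repsB)
  n <- na + nb
  total_splits <- choose(n, na)
  split_score <- function(idx) {
    manhattan_distance(process_profile(pool[idx, , drop = FALSE]),
                       process_profile(pool[-idx, , drop = FALSE]))
  }
  if (total_splits <= n_permutations) {
    combos <- utils::combn(n, na)
    perm <- apply(combos, 2, split_score)
  } else {
    set.seed(seed)
    perm <- vapply(seq_len(n_permutations), function(k)
      split_score(sample.int(n, na)), numeric(1))
  }
  p <- (1 + sum(perm >= score - 1e-12)) / (length(perm) + 1)
  list(score = score, p_value = min(p, 1), n_permutations_used = length(perm))
}

#' Presence/absence flags across phases
#'
#' A molecule is present in a phase when its maximum raw intensity over
#' fractions and replicates exceeds the detection threshold; presence in
#' one phase and absence in another marks it differential.
#'
#' @param profiles an `elution_profiles` data.frame.
#' @param detection_threshold nonnegative intensity threshold (default 0).
#' @return data.frame molecule_id x phase flags (long) with a
#'   `differential` column per molecule.
#' @export
presence_absence <- function(profiles, detection_threshold = 0) {
  validate_profiles(profiles)
  assert_scalar_number(detection_threshold, "detection_threshold", lower = 0)
  mx <- tapply(profiles$intensity,
               list(profiles$molecule_id, profiles$phase), max)
  present <- !is.na(mx) & mx > detection_threshold
  long <- data.frame(
    molecule_id = rep(rownames(present), times = ncol(present)),
    phase = rep(colnames(present), each = nrow(present)),
    present = as.vector(present), stringsAsFactors = FALSE)
  diff_ids <- rownames(present)[apply(present, 1, function(z)
    any(z) && !all(z))]
  long$differential <- long$molecule_id %in% diff_ids
  long
}
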