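# Shared fixtures: small simulated worlds and independent oracles.

tiny_config <- function(...) {
  sim_config(replicates = list(metabolite = 3L, protein_profile = 1L,
                               itsa = 5L, abundance = 5L), ...)
}

tiny_truth <- function(n_proteins = 12, n_metabolites = 8, seed = 42,
                       rewire_rate = 0.25, config = tiny_config()) {
  generate_ground_truth(config, n_proteins, n_metabolites,
                        rewire_rate = rewire_rate, seed = seed)
}

# a single-protein, single-state truth whose peak lands exactly on
# `apex_fraction`, with full control of noise
point_truth <- function(apex_fraction = 17, bound_fraction = 0.6,
                        noise_sigma = 0, seed = 1) {
  config <- tiny_config(noise_sigma = noise_sigma)
  truth <- generate_ground_truth(config, 1, 1, rewire_rate = 0, seed = seed)
  mass <- fraction_to_mass(config$mw_calibration, apex_fraction)
  for (ph in config$phases)
    truth$states[["prot_0001"]][[ph]] <-
      data.frame(mass_kDa = mass, mixing = 1)
  truth$metabolites$partner <- "prot_0001"
  truth$bound_fraction[] <- bound_fraction
  truth
}

# long-format profiles from a named list molecule -> (replicates x
# fractions matrix | vector)
profiles_df <- function(vectors, phase, class = "protein") {
  out <- list()
  for (mol in names(vectors)) {
    v <- vectors[[mol]]
    if (is.null(dim(v))) v <- matrix(v, nrow = 1)
    for (r in seq_len(nrow(v)))
      out[[length(out) + 1]] <- data.frame(
        molecule_id = mol, molecule_class = class, phase = phase,
        replicate = r, fraction = seq_len(ncol(v)), intensity = v[r, ])
  }
  df <- do.call(rbind, out)
  class(df) <- c("elution_profiles", "data.frame")
  df
}

bind_profiles <- function(...) {
  df <- rbind(...)
  class(df) <- c("elution_profiles", "data.frame")
  df
}

gauss <- function(center, n = 60, w = 2, h = 1)
  h * exp(-(seq_len(n) - center)^2 / (2 * w^2))

# independent oracle: exhaustive local-maximum scan with the 10% rule
# (plateaus: leftmost point; no separation suppression)
oracle_peak_scan <- function(x, min_rel_height = 0.10) {
  n <- length(x)
  apex <- integer(0)
  for (i in seq_len(n)) {
    if (i > 1 && x[i] == x[i - 1]) next  # plateau: only leftmost counts
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    lo <- if (i == 1) -Inf else x[i - 1]
    hi <- if (j == n) -Inf else x[j + 1]
    if (x[i] > lo && x[i] > hi && x[i] > 0) apex <- c(apex, i)
  }
  apex[x[apex] >= min_rel_height * max(x[apex])]
}

# independent oracle: Pearson correlation from the covariance formula
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# independent oracle: brute-force Ward (ward.D2) agglomeration via the
# Lance-Williams recursion on squared distances
oracle_ward <- function(d) {
  n <- nrow(d)
  d2 <- d^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  cur <- d2
  heights <- numeric(0)
  merges <- list()
  repeat {
    m <- length(active)
    if (m == 1) break
    best <- c(NA, NA); best_val <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      if (cur[i, j] < best_val) { best_val <- cur[i, j]; best <- c(i, j) }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(best_val))
    merges[[length(merges) + 1]] <- sort(c(active[[i]], active[[j]]))
    ni <- sizes[i]; nj <- sizes[j]
    new_row <- numeric(m)
    for (k in seq_len(m)) {
      if (k %in% c(i, j)) next
      nk <- sizes[k]
      new_row[k] <- ((ni + nk) * cur[i, k] + (nj + nk) * cur[j, k] -
                       nk * best_val) / (ni + nj + nk)
    }
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], new_row[keep]),
                 c(new_row[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    active <- c(active[keep], list(sort(c(active[[i]], active[[j]]))))
  }
  list(heights = heights, merges = merges)
}

# independent oracle: Newman modularity of a partition of an unweighted graph
oracle_modularity <- function(edges, membership) {
  nodes <- names(membership)
  m <- nrow(edges)
  if (m == 0) return(NA_real_)
  deg <- setNames(numeric(length(nodes)), nodes)
  for (r in seq_len(m)) {
    deg[edges$node_a[r]] <- deg[edges$node_a[r]] + 1
    deg[edges$node_b[r]] <- deg[edges$node_b[r]] + 1
  }
  q <- 0
  for (r in seq_len(m))
    if (membership[edges$node_a[r]] == membership[edges$node_b[r]])
      q <- q + 1 / m
  for (c in unique(membership)) {
    dc <- sum(deg[membership == c])
    q <- q - (dc / (2 * m))^2
  }
  q
}
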