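# Correlation networks, communities, interaction rates, Ward grouping.

peakset_of <- function(x, ...) deconvolve_peaks(x, ...)

test_that("peak correlations match the covariance-formula oracle", {
  a <- gauss(20); b <- gauss(22); m <- rev(a)
  pa <- list(A = peakset_of(a))
  pb <- list(B = peakset_of(b))
  corr <- peak_correlations(pa, pb)
  expect_equal(nrow(corr), 1L)
  rng <- 1:60
  expect_equal(corr$pcc, oracle_pearson(a, b), tolerance = 1e-12)

  # identical subprofiles correlate at exactly 1
  self <- peak_correlations(pa, list(B = peakset_of(a)))
  expect_equal(self$pcc, 1)

  # random subprofiles against the oracle
  set.seed(40)
  for (i in 1:20) {
    x <- gauss(sample(10:50, 1), w = runif(1, 1, 4)) + runif(60, 0, 0.05)
    y <- gauss(sample(10:50, 1), w = runif(1, 1, 4)) + runif(60, 0, 0.05)
    pc <- peak_correlations(list(X = peakset_of(x)), list(Y = peakset_of(y)))
    for (r in seq_len(nrow(pc))) {
      px <- peakset_of(x); py <- peakset_of(y)
      ra <- px$peaks[pc$peak_a[r], ]; rb <- py$peaks[pc$peak_b[r], ]
      rng <- min(ra$left_bound, rb$left_bound):max(ra$right_bound,
                                                   rb$right_bound)
      expect_equal(pc$pcc[r],
                   oracle_pearson(px$subprofiles[[pc$peak_a[r]]][rng],
                                  py$subprofiles[[pc$peak_b[r]]][rng]),
                   tolerance = 1e-12)
    }
  }

  # degenerate constant subprofile over the shared range is skipped
  mk_flat <- function(vals) structure(list(
    peaks = data.frame(apex_fraction = 5L, left_bound = 1L,
                       right_bound = 10L, height = 1),
    subprofiles = list(c(vals, numeric(50))), n_fractions = 60),
    class = "peak_set")
  skip_corr <- peak_correlations(list(F = mk_flat(rep(1, 10))),
                                 list(G = mk_flat(gauss(5, n = 10))))
  expect_equal(nrow(skip_corr), 0L)
  expect_equal(attr(skip_corr, "n_skipped"), 1L)
})

test_that("build_network filters edges like a brute-force scan", {
  set.seed(41)
  corr <- data.frame(
    molecule_a = paste0("m", 1:50), peak_a = 1L,
    molecule_b = paste0("p", 1:50), peak_b = 1L,
    pcc = runif(50, -1, 1))
  for (th in c(-1, 0, 0.5, 0.7, 1)) {
    net <- build_network(corr, threshold = th)
    expect_equal(nrow(net$edges), sum(corr$pcc >= th))
    if (nrow(net$edges))
      expect_true(all(net$edges$pcc >= th))
  }
  net <- build_network(corr, threshold = 0.7)
  expect_equal(sum(!net$nodes$isolated),
               length(unique(c(net$edges$node_a, net$edges$node_b))))
})

test_that("Louvain: cliques, singletons, modularity oracle", {
  clique_edges <- function(ids) {
    cmb <- t(combn(ids, 2))
    data.frame(molecule_a = cmb[, 1], peak_a = 1L,
               molecule_b = cmb[, 2], peak_b = 1L, pcc = 0.95)
  }
  corr <- rbind(clique_edges(paste0("a", 1:5)),
                clique_edges(paste0("b", 1:5)))
  net <- build_network(corr, threshold = 0.7)
  comm <- detect_communities(net, seed = 1)
  expect_length(unique(comm), 2L)
  split_a <- comm[paste0("a", 1:5, "#1")]
  expect_length(unique(split_a), 1L)
  expect_false(unique(split_a) == unique(comm[paste0("b", 1:5, "#1")]))

  # determinism
  expect_identical(comm, detect_communities(net, seed = 1))

  # modularity >= all-in-one partition, matches the formula oracle
  q <- attr(comm, "modularity")
  all_in_one <- setNames(rep(1L, length(comm)), names(comm))
  expect_gte(q, oracle_modularity(net$edges, all_in_one))
  # unweighted oracle on the same partition (edge weights are equal here)
  expect_equal(q, oracle_modularity(net$edges, comm), tolerance = 1e-12)

  # singleton nodes form their own communities
  corr2 <- rbind(corr, data.frame(molecule_a = "lone", peak_a = 1L,
                                  molecule_b = "a1", peak_b = 1L,
                                  pcc = 0.1))
  net2 <- build_network(corr2, threshold = 0.7)
  comm2 <- detect_communities(net2, seed = 1)
  expect_length(unique(comm2), 3L)
  expect_length(comm2[comm2 == comm2[["lone#1"]]], 1L)
})

test_that("interaction_rate reproduces the percentage formula", {
  expect_equal(interaction_rate(0, 3, 4), 0)
  expect_equal(interaction_rate(12, 3, 4), 100)
  expect_equal(interaction_rate(6, 3, 4), 50)
  expect_error(interaction_rate(5, 0, 4),
               class = "secshift_parameter_error")
  expect_error(interaction_rate(13, 3, 4),
               class = "secshift_parameter_error")
})

test_that("rate_matrix equals hand-counted rates and is label-invariant", {
  corr <- data.frame(
    molecule_a = c("d1", "d1", "d2", "d3", "d3"),
    peak_a = c(1L, 2L, 1L, 1L, 1L),
    molecule_b = c("pA", "pB", "pA", "pC", "pA"),
    peak_b = 1L,
    pcc = c(0.9, 0.8, 0.95, 0.75, 0.3))
  net <- build_network(corr, threshold = 0.7)
  groups <- c(d1 = "G1", d2 = "G1", d3 = "G2")
  pathways <- list(P1 = c("pA", "pB"), P2 = c("pC", "pA"))
  rm_ <- rate_matrix(net, groups, pathways)
  # hand count: G1 has 3 dipeptide peaks (d1#1, d1#2, d2#1)
  g1p1 <- rm_[rm_$group == "G1" & rm_$pathway == "P1", ]
  expect_equal(g1p1$n_dipeptide_peaks, 3L)
  expect_equal(g1p1$n_protein_peaks, 2L)   # pA#1, pB#1
  expect_equal(g1p1$n_interactions, 3L)    # d1-pA, d1-pB, d2-pA
  expect_equal(g1p1$rate, 100 * 3 / 6)
  g2p2 <- rm_[rm_$group == "G2" & rm_$pathway == "P2", ]
  expect_equal(g2p2$n_interactions, 1L)    # d3-pC only (d3-pA below 0.7)
  expect_equal(g2p2$rate, 100 * 1 / 2)

  # node relabeling leaves the rates unchanged
  relabel <- function(x) chartr("dp", "xy", x)
  corr2 <- transform(corr, molecule_a = relabel(molecule_a),
                     molecule_b = relabel(molecule_b))
  groups2 <- setNames(groups, relabel(names(groups)))
  pathways2 <- lapply(pathways, relabel)
  rm2 <- rate_matrix(build_network(corr2, 0.7), groups2, pathways2)
  expect_equal(rm2$rate, rm_$rate)

  # raising the threshold never increases any rate
  prev <- rep(Inf, nrow(rm_))
  for (th in c(0.3, 0.5, 0.7, 0.8, 0.95)) {
    r <- rate_matrix(build_network(corr, th), groups, pathways)$rate
    expect_true(all(r <= prev + 1e-12))
    prev <- r
  }
})

test_that("phase-dependent binding shows up as a phase-dependent rate", {
  # dipeptide bound to a glycolysis protein only in the late phase
  bound <- gauss(15); free <- gauss(50)
  mk <- function(dvec) {
    pk <- list(dip = peakset_of(dvec), glyA = peakset_of(gauss(15)))
    net <- build_network(peak_correlations(pk["dip"], pk["glyA"]), 0.7)
    rate_matrix(net, c(dip = "D"), list(gly = "glyA"))$rate
  }
  expect_equal(mk(free), 0)
  expect_gt(mk(bound), 0)
})

test_that("ward_group matches the brute-force merge oracle on small inputs", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    pts <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(pts))
    hc <- attr(ward_group(d, cut_height = 0), "hclust")
    oracle <- oracle_ward(d)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
    # merge composition: the leaf set created at each step must agree
    hc_sets <- vector("list", n - 1)
    for (k in seq_len(n - 1)) {
      members <- function(idx)
        if (idx < 0) -idx else hc_sets[[idx]]
      hc_sets[[k]] <- sort(c(members(hc$merge[k, 1]),
                             members(hc$merge[k, 2])))
      expect_equal(hc_sets[[k]], oracle$merges[[k]])
    }
  }
})

test_that("ward_group cut behaviour and validation", {
  # two tight, far-apart item sets -> 2 groups
  pts <- rbind(matrix(rnorm(9, 0, 0.01), 3),
               matrix(rnorm(9, 10, 0.01), 3))
  d <- as.matrix(dist(pts))
  expect_length(unique(ward_group(d, cut_height = 5)), 2L)
  # cut at 0: every item its own group
  expect_length(unique(ward_group(d, cut_height = 0)), 6L)
  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(ward_group(bad), class = "secshift_validation_error")
  neg <- d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(ward_group(neg), class = "secshift_validation_error")
})
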