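# Synthetic-data module: ground-truth generation and forward simulation.

test_that("ground truth is deterministic and respects rewire_rate edge cases", {
  cfg <- tiny_config()
  t1 <- generate_ground_truth(cfg, 10, 5, rewire_rate = 0.3, seed = 11)
  t2 <- generate_ground_truth(cfg, 10, 5, rewire_rate = 0.3, seed = 11)
  expect_identical(t1, t2)

  t0 <- generate_ground_truth(cfg, 10, 5, rewire_rate = 0, seed = 11)
  expect_length(t0$rewired_fractionation, 0)
  expect_length(t0$rewired_stability, 0)

  expect_error(generate_ground_truth(cfg, 0, 5, 0.2, 1),
               class = "secshift_parameter_error")
  expect_error(generate_ground_truth(cfg, 10, 5, 1.5, 1),
               class = "secshift_parameter_error")
})

test_that("rewired set size is binomially calibrated over seeds", {
  # 50 seeds x Binomial(100, 0.2); the mean of 50 such draws lies within
  # the 99% band mean +/- 2.576 * sqrt(n p (1-p) / 50)
  cfg <- tiny_config()
  sizes <- vapply(1:50, function(s)
    length(generate_ground_truth(cfg, 100, 1, rewire_rate = 0.2,
                                 seed = s)$rewired_fractionation),
    numeric(1))
  band <- 2.576 * sqrt(100 * 0.2 * 0.8 / 50)
  expect_lt(abs(mean(sizes) - 20), band)
})

test_that("ground-truth invariants hold across generated worlds", {
  for (seed in c(1, 7, 23)) {
    tr <- tiny_truth(n_proteins = 20, n_metabolites = 12, seed = seed)
    for (pid in names(tr$states))
      for (st in tr$states[[pid]])
        expect_equal(sum(st$mixing), 1)
    expect_true(all(tr$bound_fraction >= 0 & tr$bound_fraction <= 1))
    expect_true(all(tr$totals > 0) && all(tr$abundance > 0))
    expect_true(all(tr$rewired_fractionation %in% tr$proteins$id))
    partners <- stats::na.omit(tr$metabolites$partner)
    expect_true(all(partners %in% tr$proteins$id))
  }
})

test_that("noiseless SEC placement: apex, pools, conservation", {
  truth <- point_truth(apex_fraction = 17, bound_fraction = 0.6)
  prof <- simulate_sec_profiles(truth)
  p <- profile_matrix(prof, "prot_0001", "glucose")
  expect_equal(unname(which.max(p[1, ])), 17)

  m <- profile_matrix(prof, "met_0001", "glucose")[1, ]
  expect_equal(sum(m[1:40]) / sum(m), 0.6)
  # conservation: profile sums back to the programmed total
  expect_equal(sum(m), truth$totals["met_0001", "glucose"],
               tolerance = 1e-9)

  # bound_fraction = 0 puts everything in the free region
  truth0 <- point_truth(bound_fraction = 0)
  m0 <- profile_matrix(simulate_sec_profiles(truth0),
                       "met_0001", "glucose")[1, ]
  expect_equal(sum(m0[1:40]), 0)
  expect_gt(sum(m0[41:60]), 0)
})

test_that("noiseless peak apexes map back through the calibration", {
  cfg <- tiny_config(noise_sigma = 0)
  truth <- generate_ground_truth(cfg, 15, 2, rewire_rate = 0, seed = 5)
  prof <- simulate_sec_profiles(truth)
  for (pid in truth$proteins$id[1:8]) {
    x <- profile_matrix(prof, pid, "glucose")[1, ]
    ps <- deconvolve_peaks(normalize_to_max(x), min_rel_height = 0.10,
                           min_separation = 2)
    states <- truth$states[[pid]][["glucose"]]
    exp_fracs <- secshift:::mass_to_fraction(cfg, states$mass_kDa)
    # every programmed state above the 10% mixing rule maps to within
    # +/- 0.5 fraction of some detected apex
    for (k in seq_along(exp_fracs)) {
      if (states$mixing[k] < 0.2) next
      expect_lt(min(abs(ps$peaks$apex_fraction - exp_fracs[k])), 0.5 + 1e-9)
    }
  }
})

test_that("simulate determinism is bit-identical", {
  truth <- tiny_truth(seed = 9)
  expect_identical(simulate_sec_profiles(truth), simulate_sec_profiles(truth))
  expect_identical(simulate_itsa(truth), simulate_itsa(truth))
  expect_identical(simulate_abundance(truth)$intensities,
                   simulate_abundance(truth)$intensities)
})

test_that("iTSA sigmoid midpoint and monotonicity", {
  cfg <- tiny_config(noise_sigma = 0)
  truth <- generate_ground_truth(cfg, 4, 1, rewire_rate = 0, seed = 2)
  truth$melt$midpoint_C[] <- 52
  truth$melt$slope[] <- 1
  it <- simulate_itsa(truth)
  rt <- it[it$temperature == 22 & it$replicate == 1, ]
  t52 <- it[it$temperature == 52 & it$replicate == 1, ]
  key <- paste(rt$protein_id, rt$phase)
  ratio <- t52$intensity[match(key, paste(t52$protein_id, t52$phase))] /
    rt$intensity
  expect_equal(unname(ratio), rep(0.5, length(ratio)))

  # +4 C shift raises the soluble fraction at any fixed temperature
  truth$melt$midpoint_C[truth$melt$phase == "early_stationary"] <- 56
  it2 <- simulate_itsa(truth)
  for (tp in c(48, 52, 56)) {
    sub <- it2[it2$temperature == tp & it2$replicate == 1, ]
    sol <- sub$intensity / truth$abundance[cbind(sub$protein_id, sub$phase)]
    expect_true(all(sol[sub$phase == "early_stationary"] >
                      sol[sub$phase == "glucose"]))
  }
})

test_that("replicate-mean iTSA ratios concentrate on the noiseless value", {
  # Monte-Carlo oracle at reduced scale (200 proteins, 5 replicates)
  cfg <- tiny_config(noise_sigma = 0.1)
  truth <- generate_ground_truth(cfg, 200, 1, rewire_rate = 0, seed = 31)
  it <- simulate_itsa(truth)
  melt <- truth$melt[truth$melt$phase == "glucose", ]
  expected <- secshift:::melt_sigmoid(52, melt$midpoint_C, melt$slope)
  names(expected) <- melt$protein_id
  sub <- it[it$phase == "glucose" & it$temperature == 52, ]
  rt <- it[it$phase == "glucose" & it$temperature == 22, ]
  ratios <- sub$intensity /
    rt$intensity[match(paste(sub$protein_id, sub$replicate),
                       paste(rt$protein_id, rt$replicate))]
  mr <- tapply(ratios, sub$protein_id, mean)
  se <- tapply(ratios, sub$protein_id, function(v) sd(v) / sqrt(length(v)))
  within <- abs(mr - expected[names(mr)]) <= 3 * se
  # SE is estimated from 5 replicates, so per-protein coverage of a 3-SE
  # band is P(|T_4| <= 3) ~ 0.96, not 99.7%; allow 3 binomial SE below it
  expect_gt(mean(within), 0.96 - 3 * sqrt(0.96 * 0.04 / length(mr)))
})
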