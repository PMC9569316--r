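# Differential fractionation: Manhattan criterion, dis-elution surrogate,
# presence/absence.

test_that("Manhattan distance: identity, disjoint bound, symmetry, triangle", {
  a <- gauss(10); b <- gauss(40); c_ <- gauss(25)
  pa <- secshift::process_profile(a)
  pb <- secshift::process_profile(b)
  pc <- secshift::process_profile(c_)
  md <- function(x, y) sum(abs(x - y))
  expect_equal(md(pa, pa), 0)
  # near-disjoint unit-sum profiles approach the L1 maximum of 2
  expect_equal(md(pa, pb), 2, tolerance = 1e-6)
  expect_equal(md(pa, pb), md(pb, pa))
  expect_lte(md(pa, pb), md(pa, pc) + md(pc, pb) + 1e-12)
})

test_that("manhattan_differential flags by the median rule", {
  vecs1 <- list(m1 = gauss(10), m2 = gauss(12), m3 = gauss(14),
                m4 = gauss(16), m5 = gauss(18))
  vecs2 <- list(m1 = gauss(11), m2 = gauss(13), m3 = gauss(15),
                m4 = gauss(17), m5 = gauss(45))  # m5 moved far
  prof <- rbind(profiles_df(vecs1, "a"), profiles_df(vecs2, "b"))
  class(prof) <- c("elution_profiles", "data.frame")
  cmp <- manhattan_differential(prof, "a", "b")
  expect_true(cmp$differential_by_md[cmp$molecule_id == "m5"])
  expect_false(any(cmp$differential_by_md[cmp$molecule_id != "m5"]))
  expect_equal(cmp$manhattan_distance[cmp$molecule_id == "m1"],
               sum(abs(secshift::process_profile(gauss(10)) -
                         secshift::process_profile(gauss(11)))))

  # factor limits: infinite factor flags nothing, zero factor flags all MD>0
  expect_false(any(manhattan_differential(prof, "a", "b",
                                          factor = 1e9)$differential_by_md))
  all0 <- manhattan_differential(prof, "a", "b", factor = 0)
  expect_true(all(all0$differential_by_md[all0$manhattan_distance > 0]))
})

test_that("molecule missing in one phase is routed to presence/absence", {
  prof <- rbind(profiles_df(list(m1 = gauss(10), m2 = gauss(20)), "a"),
                profiles_df(list(m1 = gauss(10)), "b"))
  class(prof) <- c("elution_profiles", "data.frame")
  cmp <- manhattan_differential(prof, "a", "b")
  row <- cmp[cmp$molecule_id == "m2", ]
  expect_true(row$present_A); expect_false(row$present_B)
  expect_true(is.na(row$manhattan_distance))
})

test_that("Manhattan criterion recovers programmed rewiring (simulator oracle)", {
  cfg <- tiny_config(noise_sigma = 0.1)
  truth <- generate_ground_truth(cfg, 200, 2, rewire_rate = 0.2, seed = 19)
  prof <- simulate_sec_profiles(truth)
  prot <- prof[prof$molecule_class == "protein", ]
  cmp <- manhattan_differential(prot, "glucose", "early_stationary",
                                factor = 1.5)
  called <- cmp$molecule_id[cmp$differential_by_md]
  truth_set <- truth$rewired_fractionation
  sens <- length(intersect(called, truth_set)) / length(truth_set)
  spec <- 1 - length(setdiff(called, truth_set)) /
    (nrow(truth$proteins) - length(truth_set))
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})

test_that("dis-elution score: exact duplicates, programmed shift, null", {
  reps <- rbind(gauss(20), gauss(20) * 1.05, gauss(20) * 0.95)
  same <- dis_elution_score(reps, reps, seed = 1)
  expect_equal(same$score, 0)
  expect_equal(same$p_value, 1)

  # programmed bound -> free shift at noise 0.1 is significant.  Note the
  # add-one-smoothed permutation p is bounded below by 3/21 ~ 0.14 for
  # 3 vs 3 replicates (the observed split and its mirror always count),
  # so the sub-0.05 claim is tested at 5 replicates per phase.
  set.seed(21)
  noisy <- function(center, k = 5) t(sapply(1:k, function(r)
    gauss(center) * rlnorm(60, 0, 0.1)))
  shift <- dis_elution_score(noisy(20), noisy(50), n_permutations = 1000,
                             seed = 2)
  expect_lt(shift$p_value, 0.05)
  # 3 vs 3 replicates: the shift still attains the smallest reachable p
  shift3 <- dis_elution_score(noisy(20, 3), noisy(50, 3), seed = 2)
  expect_equal(shift3$p_value, 3 / 21, tolerance = 1e-9)

  # single-replicate phases: score computed, p absent
  solo <- dis_elution_score(gauss(20), gauss(25))
  expect_true(is.finite(solo$score))
  expect_true(is.na(solo$p_value))
})

test_that("dis-elution permutation p-values are super-uniform under the null", {
  set.seed(22)
  pvals <- replicate(200, {
    reps <- t(sapply(1:6, function(r) gauss(30) * rlnorm(60, 0, 0.15)))
    dis_elution_score(reps[1:3, ], reps[4:6, ], n_permutations = 500,
                      seed = sample.int(1e6, 1))$p_value
  })
  # P(p <= 0.05) must not exceed 0.05 by more than 3 binomial SE
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / 200))
})

test_that("presence_absence follows the detection threshold", {
  prof <- rbind(profiles_df(list(m1 = gauss(10), m2 = rep(0, 60)), "a"),
                profiles_df(list(m1 = gauss(10), m2 = gauss(20)), "b"))
  class(prof) <- c("elution_profiles", "data.frame")
  pa <- presence_absence(prof)
  expect_false(pa$present[pa$molecule_id == "m2" & pa$phase == "a"])
  expect_true(pa$present[pa$molecule_id == "m2" & pa$phase == "b"])
  expect_true(all(pa$differential[pa$molecule_id == "m2"]))
  expect_false(any(pa$differential[pa$molecule_id == "m1"]))

  # censoring against a programmed limit
  pa2 <- presence_absence(prof, detection_threshold = 2)
  expect_false(any(pa2$present))
})
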