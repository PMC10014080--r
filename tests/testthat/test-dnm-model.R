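test_that("trio filters drop outliers and old mothers", {
  tr <- data.frame(trio_id = c("a", "b", "c", "d"),
                   father_age = c(30, 30, 30, 30),
                   mother_age = c(41, 40, 25, 30),
                   class = "T>A", phased_paternal = 0L,
                   phased_maternal = 0L, unphased = 1L,
                   stringsAsFactors = FALSE)
  kept <- apply_trio_filters(tr, outlier_ids = "d")
  expect_equal(kept$trio_id, c("b", "c"))  # 41 > 40 out, 40 retained
})

test_that("Poisson ML recovers pedigree-scale parameters", {
  truth <- c(alpha_p = 7.6, beta_p = 1.35, alpha_m = 2.0, beta_m = 0.4)
  eff <- list("T>C_nonTpG" = pedigree_scale_effect())
  tr <- simulate_trio_dataset(trio_scenario(10000, effects = eff, seed = 42))
  fit <- fit_parental_age_model(tr, "T>C_nonTpG")
  boot <- bootstrap_effects(tr, "T>C_nonTpG", n_reps = 60, seed = 7)
  reps <- Filter(Negate(is.null), boot$replicates)
  for (p in names(truth)) {
    se <- sd(vapply(reps, `[[`, numeric(1), p))
    expect_lt(abs(fit[[p]] - truth[[p]]), 3 * se)
  }
  # the phased split does not move the MLE (phi enters as a constant)
  tr_lowphi <- simulate_trio_dataset(
    trio_scenario(10000, effects = eff, phased_fraction = 0.1, seed = 42))
  fit2 <- fit_parental_age_model(tr_lowphi, "T>C_nonTpG")
  expect_lt(abs(fit2$beta_p - truth[["beta_p"]]), 0.1)
})

test_that("likelihood at the MLE dominates the truth on synthetic data", {
  eff <- list("C>G" = parental_age_effect("C>G", 0.7, 0.12, 0.0, 0.10))
  wins <- 0L
  for (i in 1:20) {
    tr <- simulate_trio_dataset(trio_scenario(3000, effects = eff,
                                              seed = 300 + i))
    fit <- fit_parental_age_model(tr, "C>G")
    ll_fit <- dnm_loglik(fit, tr)
    ll_truth <- dnm_loglik(eff[["C>G"]], tr, "C>G")
    if (ll_fit >= ll_truth - 1e-6) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("degenerate designs are rejected and boundary data fit to zero", {
  eff <- list("T>A" = parental_age_effect("T>A", 0.6, 0.1, 0.15, 0.02))
  tr <- simulate_trio_dataset(trio_scenario(100, effects = eff, seed = 3))
  same <- tr; same$father_age <- 30; same$mother_age <- 28
  expect_error(fit_parental_age_model(same, "T>A"), "unidentifiable")
  zero <- tr
  zero$phased_paternal <- 0L; zero$phased_maternal <- 0L; zero$unphased <- 0L
  f0 <- fit_parental_age_model(zero, "T>A")
  expect_equal(unlist(f0[c("alpha_p", "beta_p", "alpha_m", "beta_m")]),
               c(alpha_p = 0, beta_p = 0, alpha_m = 0, beta_m = 0))
})

test_that("predicted ratios behave algebraically", {
  e1 <- parental_age_effect("a", 5, 1.0, 3, 0.5)
  e2 <- parental_age_effect("b", 5, 0.5, 3, 0.25)
  expect_equal(predict_ratio(e1, e1, 33, 27), 1)
  expect_equal(predict_ratio(e1, e2, 30, 30), 53 / 30.5)
  # invariant to common rescaling of both classes
  s <- 3.7
  e1s <- parental_age_effect("a", 5 * s, 1.0 * s, 3 * s, 0.5 * s)
  e2s <- parental_age_effect("b", 5 * s, 0.5 * s, 3 * s, 0.25 * s)
  expect_equal(predict_ratio(e1s, e2s, 30, 30), predict_ratio(e1, e2, 30, 30))
})

test_that("bootstrap replicates are seeded and pairable", {
  eff <- list("C>G" = parental_age_effect("C>G", 0.7, 0.12, 0.0, 0.10),
              "T>A" = parental_age_effect("T>A", 0.6, 0.10, 0.15, 0.02))
  tr <- simulate_trio_dataset(trio_scenario(400, effects = eff, seed = 9))
  b1 <- bootstrap_effects(tr, "C>G", n_reps = 5, seed = 13)
  b2 <- bootstrap_effects(tr, "C>G", n_reps = 5, seed = 13)
  expect_equal(vapply(b1$replicates, `[[`, numeric(1), "beta_m"),
               vapply(b2$replicates, `[[`, numeric(1), "beta_m"))
  # same seed on another class resamples the same trios
  b3 <- bootstrap_effects(tr, "T>A", n_reps = 5, seed = 13)
  expect_identical(b1$indices, b3$indices)
  # n_reps = 1: CI collapses onto the single replicate
  b4 <- bootstrap_effects(tr, "C>G", n_reps = 1, seed = 4)
  ci <- effect_ci(b4)
  expect_equal(ci[, "lower"], ci[, "upper"])
})

test_that("age-quintile CpG ratio contrast detects an age-dependent spectrum", {
  # age-independent spectrum: ratios agree and p is not extreme
  eff_null <- list(
    "C>T_CpG" = parental_age_effect("C>T_CpG", 10, 0, 0.5, 0),
    "C>A_CpG" = parental_age_effect("C>A_CpG", 0.5, 0, 0.025, 0)
  )
  tr <- simulate_trio_dataset(trio_scenario(3000, effects = eff_null, seed = 61))
  res <- quintile_cpg_ratio_test(tr)
  expect_lt(abs(res$ratio_young / res$ratio_old - 1), 0.25)

  # CpG C>T fraction declining ~0.26%/yr of parental age: C>T flat in age
  # while C>A grows with age, so the young/old ratio contrast is positive
  eff_alt <- list(
    "C>T_CpG" = parental_age_effect("C>T_CpG", 12, 0, 0.6, 0),
    "C>A_CpG" = parental_age_effect("C>A_CpG", 0.2, 0.012, 0.01, 0.006)
  )
  tr2 <- simulate_trio_dataset(trio_scenario(3000, effects = eff_alt, seed = 62))
  res2 <- quintile_cpg_ratio_test(tr2)
  expect_gt(res2$ratio_young, res2$ratio_old)
  expect_lt(res2$p_value, 0.05)
})
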