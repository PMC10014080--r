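test_that("solving the ratio equation round-trips the generation time", {
  eff <- default_parental_age_effects()
  e1 <- eff[["C>G"]]; e2 <- eff[["T>A"]]
  for (G in seq(15, 50, by = 5)) {
    R <- predict_ratio(e1, e2, G, G)
    s <- solve_generation_time(R, e1, e2, gamma = 1)
    expect_lt(abs(s$Gm - G), 1e-6)
    expect_lt(abs(s$Gp - G), 1e-6)
  }
  # closed-form arithmetic example
  a <- parental_age_effect("a", 5, 1.0, 3, 0.5)
  b <- parental_age_effect("b", 5, 0.5, 3, 0.25)
  s <- solve_generation_time(1.7377049, a, b, gamma = 1)
  expect_equal(s$Gm, 30, tolerance = 1e-4)

  # gamma couples paternal and maternal ages
  R <- predict_ratio(e1, e2, 36, 30)
  s <- solve_generation_time(R, e1, e2, gamma = 1.2)
  expect_equal(s$Gp / s$Gm, 1.2)
  expect_equal(s$Gm, 30, tolerance = 1e-8)
})

test_that("infeasible and degenerate solutions are flagged", {
  eff <- default_parental_age_effects()
  e1 <- eff[["C>G"]]; e2 <- eff[["T>A"]]
  # a ratio beyond any attainable age solves outside the plausible range
  R_at_60 <- predict_ratio(e1, e2, 60, 60)
  s <- solve_generation_time(R_at_60 * 1.05, e1, e2, gamma = 1)
  expect_false(s$feasible)
  # ratio solving to negative Gm
  R_neg <- predict_ratio(e1, e2, 13, 13)
  s2 <- solve_generation_time(R_neg, e1, e2, gamma = 1,
                              plausible_range = c(20, 55))
  expect_false(s2$feasible)
  # identical effects with R = 1: denominator vanishes
  s3 <- solve_generation_time(1, e1, e1, gamma = 1)
  expect_false(s3$feasible)
  expect_equal(s3$reason, "no_solution")
  expect_error(solve_generation_time(-1, e1, e2), "positive")
})

test_that("solutions are monotone in R where the denominator keeps sign", {
  eff <- default_parental_age_effects()
  e1 <- eff[["C>G"]]; e2 <- eff[["T>A"]]
  Rs <- vapply(seq(15, 50, 5), function(G) predict_ratio(e1, e2, G, G),
               numeric(1))
  Gs <- vapply(Rs, function(R) {
    solve_generation_time(R, e1, e2, gamma = 1)$Gm
  }, numeric(1))
  expect_true(all(diff(Gs) > 0) || all(diff(Gs) < 0))
})

test_that("constraint lines reproduce the observed ratio", {
  eff <- default_parental_age_effects()
  e1 <- eff[["C>T_nonCpG"]]; e2 <- eff[["C>A_nonCpG"]]
  R <- predict_ratio(e1, e2, 32, 26)
  ln <- constraint_line(R, e1, e2)
  # points on the line a*Gp + b*Gm = c give back R
  for (Gp in c(20, 30, 40)) {
    Gm <- (ln$c - ln$a * Gp) / ln$b
    expect_lt(abs(predict_ratio(e1, e2, Gp, Gm) - R), 1e-9)
  }
  # two ratios' lines meet at the generating ages
  e3 <- eff[["C>G"]]; e4 <- eff[["T>A"]]
  R2 <- predict_ratio(e3, e4, 32, 26)
  l2 <- constraint_line(R2, e3, e4)
  sol <- solve(rbind(c(ln$a, ln$b), c(l2$a, l2$b)), c(ln$c, l2$c))
  expect_equal(sol, c(32, 26), tolerance = 1e-8)
  # degenerate all-plane case
  expect_equal(constraint_line(1, e1, e1)$degenerate, "plane")
})

test_that("bootstrap generation-time CIs are percentile over paired replicates", {
  eff <- list("C>G" = parental_age_effect("C>G", 0.7, 0.12, 0.0, 0.10),
              "T>A" = parental_age_effect("T>A", 0.6, 0.10, 0.15, 0.02))
  tr <- simulate_trio_dataset(trio_scenario(2000, effects = eff, seed = 71))
  b1 <- bootstrap_effects(tr, "C>G", n_reps = 40, seed = 72)
  b2 <- bootstrap_effects(tr, "T>A", n_reps = 40, seed = 72)
  R <- predict_ratio(eff[["C>G"]], eff[["T>A"]], 30, 30)
  ci <- bootstrap_generation_time(R, b1, b2, gamma = 1)
  expect_lt(ci$ci_lower, ci$ci_upper)
  expect_true(ci$ci_lower < 30 & 30 < ci$ci_upper)
  expect_lt(ci$infeasible_fraction, 0.5)

  # ratio_counts propagates the polymorphism sampling noise of R:
  # enormous counts reproduce the pedigree-only interval, and moderate
  # counts widen it
  ci_big <- bootstrap_generation_time(R, b1, b2, gamma = 1,
                                      ratio_counts = c(4e7, 2e7), seed = 3)
  expect_equal(ci_big$ci_lower, ci$ci_lower, tolerance = 0.02)
  expect_equal(ci_big$ci_upper, ci$ci_upper, tolerance = 0.02)
  ci_w <- bootstrap_generation_time(R, b1, b2, gamma = 1,
                                    ratio_counts = c(20000, 10000), seed = 3)
  expect_gt(ci_w$ci_upper - ci_w$ci_lower, ci$ci_upper - ci$ci_lower)

  # identical replicate sets give a zero-width CI
  one <- bootstrap_effects(tr, "C>G", n_reps = 1, seed = 5)
  two <- bootstrap_effects(tr, "T>A", n_reps = 1, seed = 5)
  R1 <- predict_ratio(one$replicates[[1]], two$replicates[[1]], 28, 28)
  ci1 <- bootstrap_generation_time(R1, one, two, gamma = 1)
  expect_equal(ci1$ci_lower, ci1$ci_upper)
  expect_equal(ci1$ci_lower, 28, tolerance = 1e-6)
})
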