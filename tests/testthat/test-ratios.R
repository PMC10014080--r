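test_that("ratio CI follows the binomial normal approximation", {
  # n1 = n2 = 100, z = 1.96: p = 0.5, se = sqrt(0.25/200);
  # odds transform of (0.46464, 0.53536)
  est <- ratio_with_ci(100, 100, z = 1.96)
  expect_equal(est$ratio, 1)
  p_lo <- 0.5 - 1.96 * sqrt(0.25 / 200)
  expect_equal(est$ci_lower, p_lo / (1 - p_lo))
  expect_equal(est$ci_upper, (1 - p_lo) / p_lo)
  expect_equal(est$ci_lower * est$ci_upper, 1, tolerance = 1e-12)

  # symmetry on the p scale for any equal counts
  est2 <- ratio_with_ci(31.7, 31.7)
  expect_equal(est2$ratio, 1)
  expect_equal(est2$p_hat, 0.5)

  # widening z widens the CI monotonically
  zs <- c(1, 1.64, 1.96, 2.58)
  widths <- vapply(zs, function(z) {
    e <- ratio_with_ci(120, 80, z)
    e$ci_upper - e$ci_lower
  }, numeric(1))
  expect_true(all(diff(widths) > 0))

  expect_error(ratio_with_ci(0, 0), "positive")
  expect_error(ratio_with_ci(5, 0), "denominator")
  expect_true(ratio_with_ci(0, 50)$degenerate)
})

test_that("interpopulation chi-square matches hand-computed expectations", {
  res <- interpopulation_chisq(rbind(c(30, 50), c(70, 50)))
  expect_equal(res$statistic, 25 / 3, tolerance = 1e-9)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, pchisq(25 / 3, 1, lower.tail = FALSE))

  # equal proportions: statistic 0, p = 1 (any number of populations)
  expect_equal(interpopulation_chisq(rbind(c(10, 20, 5), c(30, 60, 15)))$statistic, 0)
  expect_equal(interpopulation_chisq(rbind(c(4, 4, 4), c(9, 9, 9)))$p_value, 1)

  expect_error(interpopulation_chisq(rbind(c(0, 0), c(5, 5))), "zero row")
})

test_that("chi-square on integer tables equals the textbook computation", {
  set.seed(101)
  for (i in 1:200) {
    npop <- sample(2:5, 1)
    tab <- matrix(rpois(2 * npop, lambda = 40) + 1, nrow = 2)
    mine <- interpopulation_chisq(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("chi-square type-I error is calibrated under a shared spectrum", {
  set.seed(202)
  n <- 4000
  p <- 0.35
  hits <- replicate(1000, {
    x1 <- rbinom(1, n, p); x2 <- rbinom(1, n, p)
    tab <- rbind(c(x1, x2), c(n - x1, n - x2))
    interpopulation_chisq(tab)$p_value < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("Bonferroni adjustment multiplies by the test-grid size", {
  expect_equal(bonferroni_adjust(1e-4, 15, 4), 6e-3)
  expect_equal(bonferroni_adjust(0.5, 15, 4), 1)
  expect_equal(bonferroni_adjust(c(0, 1e-10)), c(0, 6e-9))
  expect_error(bonferroni_adjust(1.2), "p")
})

test_that("region stratification honors BED half-open 0-based convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200", "1\t150\t300", "2\t0\t50"), bed)
  regions <- read_regions(bed)
  expect_equal(length(regions), 2L)  # overlapping intervals merged

  v <- make_variants(rep("C", 4), rep("T", 4), "A", "A")
  v$chrom <- c("1", "1", "1", "2")
  v$pos <- c(101L, 100L, 300L, 1L)  # pos-1 = 100, 99, 299, 0
  parts <- stratify_by_regions(v, regions)
  expect_equal(parts$inside$pos, c(101L, 300L, 1L))
  expect_equal(parts$outside$pos, 100L)

  # empty region set: everything outside
  parts <- stratify_by_regions(v, GenomicRanges::GRanges())
  expect_equal(nrow(parts$inside), 0L)
  expect_equal(nrow(parts$outside), 4L)
})

test_that("pairwise ratios are unaffected by counts of unrelated classes", {
  sc <- single_epoch_scenario(uniformish_fractions(), 20000, seed = 41,
                              age_start = 10, age_end = 5000)
  v <- filter_variants(classify_variants(simulate_variant_dataset(sc)))
  binning <- determine_bin_boundaries(v, n_bins = 5, seed = 2)
  tab <- build_pseudocount_table(v, binning)
  tab2 <- tab
  tab2["T>G", ] <- tab2["T>G", ] * 10  # only affects the T>C/T>G ratio
  traj1 <- ratio_trajectories(list(CEU = tab))
  traj2 <- ratio_trajectories(list(CEU = tab2))
  unaffected <- traj1$ratio_name != "TC_TG"
  expect_equal(traj2$ratio[unaffected], traj1$ratio[unaffected])
  expect_false(any(traj2$ratio[!unaffected] == traj1$ratio[!unaffected]))
})

test_that("ratio trajectories carry per-bin interpopulation tests", {
  sc <- single_epoch_scenario(
    uniformish_fractions(), 30000, seed = 51, age_start = 10, age_end = 5000,
    populations = list(CEU = 0.9, YRI = 0.9)
  )
  v <- filter_variants(classify_variants(simulate_variant_dataset(sc)))
  ceu <- v[grepl("CEU", v$populations), ]
  yri <- v[grepl("YRI", v$populations), ]
  binning <- determine_bin_boundaries(ceu, n_bins = 5, seed = 6)
  tabs <- list(CEU = build_pseudocount_table(ceu, binning),
               YRI = build_pseudocount_table(yri, binning))
  traj <- ratio_trajectories(tabs)
  expect_equal(nrow(traj), 2L * 5L * 4L)
  expect_true(all(traj$ci_lower <= traj$ratio & traj$ratio <= traj$ci_upper))
  expect_true(all(traj$p_adjusted >= traj$p_raw, na.rm = TRUE))
  # same spectrum in both populations: no adjusted signal expected
  expect_gt(min(traj$p_adjusted, na.rm = TRUE), 0.01)
})
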