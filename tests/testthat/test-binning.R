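test_that("age filter removes variants older than 3,000,000 generations", {
  v <- make_variants(rep("C", 3), rep("T", 3), "A", "A",
                     age_lower = c(10, 10, 10),
                     age_upper = c(3000001, 2999999, 3e6))
  kept <- filter_variants(v)
  expect_equal(kept$age_upper, c(2999999, 3e6))
  expect_equal(nrow(filter_variants(v[0, ])), 0L)
})

test_that("bin boundaries are seeded quantiles of sampled point ages", {
  sc <- single_epoch_scenario(uniformish_fractions(), 30000, seed = 9,
                              age_start = 0, age_end = 5000)
  v <- simulate_variant_dataset(sc)
  b1 <- determine_bin_boundaries(v, n_bins = 15, seed = 3)
  b2 <- determine_bin_boundaries(v, n_bins = 15, seed = 3)
  expect_identical(b1$boundaries, b2$boundaries)
  expect_equal(length(b1$boundaries), 16L)
  expect_true(all(diff(b1$boundaries) > 0))

  # equal occupancy: re-draw point ages with the binning's seed and count
  pts <- with_seed(3, runif(nrow(v), v$age_lower, v$age_upper))
  counts <- table(cut(pts, b1$boundaries, include.lowest = TRUE))
  expect_true(all(abs(counts - 2000) <= 0.02 * 2000 + 1))

  # single bin spans the sampled range
  b <- determine_bin_boundaries(v, n_bins = 1, seed = 3)
  expect_equal(b$boundaries, range(pts))
  expect_error(determine_bin_boundaries(v, n_bins = 0), "n_bins")
})

test_that("uniform-age weights follow the overlap worked example", {
  bounds <- c(312, 545, 1160, 2970)
  w <- assign_bin_weights(500, 1300, bounds)
  expect_equal(round(w, 3), c(0.056, 0.769, 0.175))
  # exact overlap arithmetic: (545-500)/800, (1160-545)/800, (1300-1160)/800
  expect_equal(w, c(45, 615, 140) / 800)

  # interval spanning all three bins
  expect_equal(assign_bin_weights(312, 2970, bounds),
               c(233, 615, 1810) / 2658)

  # containment gives unit mass; point age likewise
  expect_equal(assign_bin_weights(600, 700, bounds), c(0, 1, 0))
  expect_equal(assign_bin_weights(700, 700, bounds), c(0, 1, 0))

  # truncation outside the boundaries renormalizes to 1
  w <- assign_bin_weights(100, 800, bounds)
  expect_equal(sum(w), 1)
  expect_equal(w, c(545 - 312, 800 - 545, 0) / (800 - 312))

  # entirely outside: zero vector, flagged
  w <- assign_bin_weights(1, 100, bounds)
  expect_equal(sum(w), 0)
  expect_true(isTRUE(attr(w, "outside")))
  expect_error(assign_bin_weights(10, 5, bounds), "age_lower")
})

test_that("bin weights are consistent with Monte Carlo uniform draws", {
  bounds <- c(0, 50, 200, 1000, 2500)
  lower <- 120; upper <- 2200
  w <- assign_bin_weights(lower, upper, bounds)
  draws <- with_seed(77, runif(1e5, lower, upper))
  emp <- table(cut(draws, bounds)) / 1e5
  se <- sqrt(w * (1 - w) / 1e5)
  expect_true(all(abs(as.numeric(emp) - w) <= 4 * se + 1e-12))
})

test_that("pseudo-count tables conserve unit mass per variant", {
  sc <- single_epoch_scenario(uniformish_fractions(), 10000, seed = 21,
                              age_start = 10, age_end = 8000)
  v <- classify_variants(simulate_variant_dataset(sc))
  v <- filter_variants(v)
  binning <- determine_bin_boundaries(v, n_bins = 15, seed = 4)
  tab <- build_pseudocount_table(v, binning)
  expect_equal(sum(tab), attr(tab, "n_variants"), tolerance = 1e-9)
  expect_true(attr(tab, "n_variants") + attr(tab, "n_outside") == nrow(v))
  expect_true(all(tab >= 0))

  # the worked-example variant alone fills a single class row
  one <- make_variants("T", "A", "A", "A", age_lower = 500, age_upper = 1300)
  one <- classify_variants(one)
  b <- structure(list(boundaries = c(312, 545, 1160, 2970), n_bins = 3L,
                      reference_population = "CEU", seed = 1L),
                 class = "age_binning")
  t1 <- build_pseudocount_table(one, b)
  expect_equal(unname(t1["T>A", ]), c(45, 615, 140) / 800)
  expect_equal(sum(t1[rownames(t1) != "T>A", ]), 0)
})

test_that("reference-population boundaries conserve other populations' mass", {
  sc <- single_epoch_scenario(
    uniformish_fractions(), 8000, seed = 31, age_start = 10, age_end = 6000,
    populations = list(CEU = 0.8, YRI = 0.8)
  )
  v <- filter_variants(classify_variants(simulate_variant_dataset(sc)))
  ceu <- v[grepl("CEU", v$populations), ]
  yri <- v[grepl("YRI", v$populations), ]
  binning <- determine_bin_boundaries(ceu, n_bins = 10, seed = 8)
  tab <- build_pseudocount_table(yri, binning)
  expect_equal(sum(tab), attr(tab, "n_variants"), tolerance = 1e-6)
})
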