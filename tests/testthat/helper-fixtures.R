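# Shared fixture builders for the test suite. Everything is generated in
# code so the suite carries no data files.

# a minimal variant data frame in collapsed-friendly columns
make_variants <- function(ancestral, derived, five_prime, three_prime,
                          age_lower = 10, age_upper = 20,
                          populations = "CEU") {
  n <- length(ancestral)
  data.frame(
    chrom = "1", pos = seq_len(n) * 1000L,
    ancestral = ancestral, derived = derived,
    five_prime = five_prime, three_prime = three_prime,
    age_lower = rep_len(age_lower, n), age_upper = rep_len(age_upper, n),
    populations = rep_len(populations, n),
    stringsAsFactors = FALSE
  )
}

# single-epoch scenario with a named fraction vector
single_epoch_scenario <- function(fractions, n, seed = 1L,
                                  age_start = 0, age_end = 1000,
                                  populations = list(CEU = 1.0)) {
  spectrum_scenario(
    epochs = list(list(age_start = age_start, age_end = age_end,
                       class_fractions = fractions)),
    n_variants = n, populations = populations, seed = seed
  )
}

# balanced fractions over the nine matched classes
uniformish_fractions <- function() {
  f <- c("C>A_CpG" = 0.02, "C>A_nonCpG" = 0.10, "C>G" = 0.10,
         "C>T_CpG" = 0.15, "C>T_nonCpG" = 0.15, "T>A" = 0.10,
         "T>C_TpG" = 0.08, "T>C_nonTpG" = 0.20, "T>G" = 0.10)
  f / sum(f)
}

# planted three-signature context matrix with Poisson sampling noise:
# sparse distinct signatures and smooth exposure trajectories so each
# signature dominates a stretch of columns
planted_context_matrix <- function(seed, K = 3L, m = 45L, depth = 20000) {
  mutspectra::with_seed(seed, {
    n <- 96L
    W0 <- matrix(rgamma(n * K, 0.08), n, K)
    W0 <- sweep(W0, 2L, colSums(W0), "/")
    x <- seq(0, 1, length.out = m)
    centers <- seq(0.15, 0.9, length.out = K)
    H0 <- t(vapply(centers, function(cc) exp(-((x - cc) / 0.25)^2),
                   numeric(m)))
    H0 <- sweep(H0, 2L, colSums(H0), "/") * depth
    V <- matrix(rpois(n * m, W0 %*% H0), n, m)
    list(V = sweep(V, 2L, pmax(colSums(V), 1), "/"), signatures = W0,
         exposures = H0)
  })
}

# one-class effect with pedigree-scale parameters (wide validity range so
# synthetic scenarios with extreme ages stay legal)
pedigree_scale_effect <- function(class = "T>C_nonTpG") {
  parental_age_effect(class, alpha_p = 7.6, beta_p = 1.35,
                      alpha_m = 2.0, beta_m = 0.4, age_range = c(10, 80))
}
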