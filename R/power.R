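#' Power to detect a generation-time-driven C>G/T>A difference
#'
#' Simulates two populations whose mutation spectra differ only because
#' their generation times differ. Per replicate and population, the
#' numbers of C>G and T>A SNPs are drawn from independent binomials with
#' the expected class fractions at `(G, G)` (computed over all classes
#' from the fitted parental-age effects) and `n_snps` trials; a 2 x 2
#' chi-square test (two mutation types x two populations) is applied and
#' power is the fraction of replicates with `p < alpha`.
#'
#' @param effects Named list of [parental_age_effect()]s for all
#'   mutation classes (must include `"C>G"` and `"T>A"`).
#' @param G1,G2 Generation times (years) of the two populations.
#' @param n_snps Number of SNPs sampled per population and type draw.
#' @param n_reps Number of simulation replicates (default 10,000).
#' @param alpha Significance threshold (default 0.001).
#' @param seed Integer seed.
#' @return Estimated power (a probability).
#' @export
simulate_power <- function(effects, G1, G2, n_snps, n_reps = 10000L,
                           alpha = 0.001, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop_mutspectra("alpha must be in (0, 1)")
  if (n_reps < 1L) stop_mutspectra("n_reps must be >= 1")
  f1 <- expected_class_fractions(effects, G1)
  f2 <- expected_class_fractions(effects, G2)
  for (f in list(f1, f2)) {
    if (any(f[c("C>G", "T>A")] <= 0) || any(f[c("C>G", "T>A")] >= 1)) {
      stop_mutspectra("degenerate expected fraction for C>G or T>A")
    }
  }
  with_seed(seed, {
    cg1 <- rbinom(n_reps, n_snps, f1[["C>G"]])
    ta1 <- rbinom(n_reps, n_snps, f1[["T>A"]])
    cg2 <- rbinom(n_reps, n_snps, f2[["C>G"]])
    ta2 <- rbinom(n_reps, n_snps, f2[["T>A"]])
    p <- chisq_2x2_p(cg1, ta1, cg2, ta2)
    mean(p < alpha, na.rm = TRUE)
  })
}

# vectorized Pearson chi-square p-value for 2x2 tables [[a,b],[c,d]]
# (rows = mutation types, columns = populations), df = 1
chisq_2x2_p <- function(a, c_, b, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c_ <- as.numeric(c_); d <- as.numeric(d)
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  bad <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  stat <- n * (a * d - b * c_)^2 / (r1 * r2 * c1 * c2)
  stat[bad] <- NA_real_
  pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Compare detection power inside vs. outside maternal C>G hotspots
#'
#' Maternal C>G mutations concentrate in hotspot regions: a
#' `hotspot_share_of_genome` fraction of the genome (holding
#' `hotspot_share_of_snps` of the SNPs) carries `maternal_effect_share`
#' (one-third) of the overall maternal age effect, i.e. of the summed
#' maternal slopes of all mutation classes. The two strata are modeled
#' region-wise: every per-class parameter scales with the stratum's
#' genome share, except the maternal C>G slope, which is
#' `maternal_effect_share * sum(beta_m)` inside the hotspots and the
#' remainder of the genome-wide C>G maternal slope outside (the total is
#' conserved). Because class fractions are scale-invariant within a
#' stratum, this concentrates the age sensitivity of the C>G fraction in
#' the hotspots, where power is then assessed with the hotspot's smaller
#' SNP count.
#'
#' @param effects Named list of per-class [parental_age_effect()]s; the
#'   C>G maternal slope must be at least
#'   `maternal_effect_share * sum(beta_m)`, otherwise the stated
#'   concentration is impossible.
#' @param G1,G2 Generation times of the two populations (years).
#' @param n_snps Genome-wide SNP count per population.
#' @param hotspot_share_of_genome Genome fraction covered by hotspots
#'   (default 0.10).
#' @param hotspot_share_of_snps Fraction of SNPs inside hotspots
#'   (default 0.15; hotspots are C>G-dense, so their SNP share exceeds
#'   their genome share).
#' @param maternal_effect_share Fraction of the overall maternal age
#'   effect concentrated in the hotspots (default 1/3).
#' @param n_reps,alpha,seed As in [simulate_power()].
#' @return List with `power_in`, `power_out`, the per-region SNP counts,
#'   and the per-genome-share enrichment of the maternal C>G slope in
#'   each stratum.
#' @export
compare_hotspot_power <- function(effects, G1, G2, n_snps,
                                  hotspot_share_of_genome = 0.10,
                                  hotspot_share_of_snps = 0.15,
                                  maternal_effect_share = 1 / 3,
                                  n_reps = 10000L, alpha = 0.001,
                                  seed = 1L) {
  g <- hotspot_share_of_genome
  s <- hotspot_share_of_snps
  if (g <= 0 || g >= 1 || s <= 0 || s >= 1) {
    stop_mutspectra("genome and SNP shares must be in (0, 1)")
  }
  beta_m_total <- sum(vapply(effects, `[[`, numeric(1L), "beta_m"))
  bm_cg <- effects[["C>G"]]$beta_m
  bm_in <- maternal_effect_share * beta_m_total
  if (bm_in > bm_cg) {
    stop_mutspectra("maternal_effect_share * sum(beta_m) exceeds the C>G ",
                    "maternal slope; the stated concentration is impossible")
  }
  enrich_in <- bm_in / (g * bm_cg)
  if (enrich_in < 1) {
    stop_mutspectra("hotspot maternal C>G slope enrichment must be >= 1")
  }
  bm_out <- bm_cg - bm_in

  region_effects <- function(share, bm_cg_region) {
    out <- lapply(effects, function(e) {
      parental_age_effect(e$class, e$alpha_p * share, e$beta_p * share,
                          e$alpha_m * share, e$beta_m * share)
    })
    e <- effects[["C>G"]]
    out[["C>G"]] <- parental_age_effect("C>G", e$alpha_p * share,
                                        e$beta_p * share,
                                        e$alpha_m * share, bm_cg_region)
    out
  }
  n_in <- max(1L, round(s * n_snps))
  n_out <- max(1L, n_snps - n_in)
  list(
    power_in = simulate_power(region_effects(g, bm_in), G1, G2,
                              n_in, n_reps, alpha, seed),
    power_out = simulate_power(region_effects(1 - g, bm_out), G1, G2,
                               n_out, n_reps, alpha, seed + 1L),
    n_snps_in = n_in, n_snps_out = n_out,
    enrichment_in = enrich_in,
    enrichment_out = bm_out / ((1 - g) * bm_cg)
  )
}
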