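#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Two population samples share an ancestral mutation spectrum; in the
# "B" sample the C>G/T>A balance shifts in the most recent ~1000
# generations, emulating a recent change in the mutation process in one
# population only. A companion pedigree panel of trios is drawn from
# sex-specific linear parental-age effects so the polymorphism and DNM
# sides of the analysis refer to the same underlying mutation biology.

library(mutspectra)

seed <- 20260921L
dir.create("results", showWarnings = FALSE)

# ancestral spectrum = the DNM class fractions implied by the parental
# age effects at a constant generation time of 30 years, so population
# A's ratios are invertible to that generation time downstream
base <- expected_class_fractions(default_parental_age_effects(), G = 30)
shift <- base
shift["C>G"] <- base[["C>G"]] * 1.6
shift["T>A"] <- base[["T>A"]] * 0.5
shift <- shift / sum(shift)

scenario <- function(frac_recent, s) spectrum_scenario(
  epochs = list(
    list(age_start = 0, age_end = 1000, class_fractions = frac_recent),
    list(age_start = 1000, age_end = 20000, class_fractions = base)
  ),
  n_variants = 30000, epoch_weights = c(0.3, 0.7), seed = s
)

vA <- simulate_variant_dataset(scenario(base, seed + 1L))
vB <- simulate_variant_dataset(scenario(shift, seed + 2L))
write_variant_table(vA, "results/variants_A.tsv")
write_variant_table(vB, "results/variants_B.tsv")

trios <- simulate_trio_dataset(
  trio_scenario(3000, effects = default_parental_age_effects(),
                seed = seed + 3L))
write_trio_table(trios, "results/trios.tsv")

write_manifest("results/manifest_01.tsv", seed = seed,
               n_variants_per_population = 30000, n_trios = 3000,
               shift_epoch = "0-1000 generations",
               shifted_classes = "C>G up 1.6x, T>A down 0.5x (population B)")

cat("Simulated", nrow(vA), "+", nrow(vB), "variants and",
    length(unique(trios$trio_id)), "trios.\n")
cat("Population B carries a recent C>G/T>A shift; population A is constant.\n")
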