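#!/usr/bin/env Rscript
# Stage 6: power to detect a generation-time-driven C>G/T>A difference
# between two populations, inside vs. outside the maternal C>G mutation
# hotspots (10% of the genome carrying one-third of the overall maternal
# age effect, <15% of SNPs).

library(mutspectra)

seed <- 20260921L
eff <- default_parental_age_effects()
G_grid <- c(20, 25, 30, 35, 40)
n_snps <- 500000L
n_reps <- 2000L

out <- data.frame()
for (i in seq_along(G_grid)) {
  for (j in seq_along(G_grid)) {
    if (j <= i) next
    hp <- compare_hotspot_power(eff, G_grid[i], G_grid[j], n_snps = n_snps,
                                n_reps = n_reps, alpha = 0.001,
                                seed = seed + 60L + 10L * i + j)
    out <- rbind(out, data.frame(
      G1 = G_grid[i], G2 = G_grid[j],
      power_hotspot = hp$power_in, power_outside = hp$power_out,
      n_snps_hotspot = hp$n_snps_in, n_snps_outside = hp$n_snps_out))
  }
}
write.table(out, "results/power_hotspots.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(out, row.names = FALSE)
cat(sprintf(
  "Hotspot power exceeds outside power in %d of %d generation-time pairs,\n",
  sum(out$power_hotspot > out$power_outside), nrow(out)))
cat("despite the hotspots holding only 15% of the SNPs.\n")
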