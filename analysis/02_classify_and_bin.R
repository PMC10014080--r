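#!/usr/bin/env Rscript
# Stage 2: classify variants into strand-collapsed mutation classes and
# spread each variant's mass over allele-age bins.
#
# Classes use the CpG/TpG-refined scheme; variants with ambiguous
# context or implausibly old age bounds (> 3,000,000 generations) are
# removed. Bin boundaries come from Monte Carlo point ages of the "A"
# sample (the reference population), and each variant contributes
# fractional pseudo-counts to the bins its uniform age interval overlaps.

library(mutspectra)

seed <- 20260921L
n_bins <- 10L

read_pop <- function(p) {
  v <- read_variant_table(sprintf("results/variants_%s.tsv", p))
  filter_variants(classify_variants(v))
}
vA <- read_pop("A")
vB <- read_pop("B")
cat("After context/age filtering:", nrow(vA), "A,", nrow(vB), "B variants\n")

binning <- determine_bin_boundaries(vA, n_bins = n_bins, seed = seed + 10L,
                                    reference_population = "A")
print(binning)
writeLines(format(binning$boundaries, digits = 12),
           "results/bin_boundaries.txt")

tabA <- build_pseudocount_table(vA, binning)
tabB <- build_pseudocount_table(vB, binning)
write_pseudocount_table(tabA, "results/pseudocounts_A.tsv")
write_pseudocount_table(tabB, "results/pseudocounts_B.tsv")

cat(sprintf("Pseudo-count mass: A %.1f (of %d variants), B %.1f (of %d)\n",
            sum(tabA), nrow(vA), sum(tabB), nrow(vB)))
write_manifest("results/manifest_02.tsv", seed = seed, n_bins = n_bins,
               reference_population = "A")
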