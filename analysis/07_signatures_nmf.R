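#!/usr/bin/env Rscript
# Stage 7: 96-context mutation-type matrix over (population x age bin)
# columns, factorized by KL-divergence NMF with consensus-based rank
# selection.

library(mutspectra)

seed <- 20260921L
read_pop <- function(p) {
  v <- read_variant_table(sprintf("results/variants_%s.tsv", p))
  filter_variants(classify_variants(v))
}
vA <- read_pop("A")
vB <- read_pop("B")
boundaries <- as.numeric(readLines("results/bin_boundaries.txt"))
binning <- structure(
  list(boundaries = boundaries, n_bins = length(boundaries) - 1L,
       reference_population = "A", seed = seed),
  class = "age_binning"
)

V <- build_context_matrix(list(A = vA, B = vB), binning)
cat("Context matrix:", nrow(V), "x", ncol(V), "\n")

r <- select_rank(V, ranks = 2:5, n_runs = 10, seed = seed + 70L)
diag <- attr(r, "diagnostics")
print(diag, row.names = FALSE)
cat("Selected rank:", as.integer(r), "\n")

fit <- nmf_factorize(V, rank = as.integer(r), n_runs = 12,
                     seed = seed + 71L)
print(fit)
sig <- data.frame(context = rownames(V), fit$signatures)
colnames(sig)[-1] <- paste0("signature", seq_len(ncol(fit$signatures)))
write.table(sig, "results/nmf_signatures.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
exp_df <- data.frame(column = colnames(V), t(fit$exposures))
colnames(exp_df)[-1] <- paste0("signature", seq_len(ncol(fit$signatures)))
write.table(exp_df, "results/nmf_exposures.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(diag, "results/nmf_rank_diagnostics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
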