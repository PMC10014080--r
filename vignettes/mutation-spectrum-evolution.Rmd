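---
title: "Models and methods: mutation-spectrum change over allele age and the generation-time test"
author: "mutspectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutspectra)
```

## The problem

The relative rates of different germline mutation types — the mutation
spectrum — differ between human populations and between polymorphisms of
different ages. Two families of explanation compete: changes in the
mutation process itself (environmental exposures, genetic modifiers), or
shifts in life history, since the number and type of de novo mutations
(DNMs) a child receives depend strongly on the parents' ages at
conception. This package implements a framework to (i) measure spectrum
change over time from polymorphisms annotated with genealogy-based
allele ages, while controlling for GC-biased gene conversion (gBGC), and
(ii) ask quantitatively whether shifts in mean reproductive ages
("generation times") can account for the observed changes, using
parental-age effects fitted to pedigree DNM data.

Every stage operates on data the package can also simulate, so the whole
pipeline is testable end to end without external downloads.

## Classification and context

Each biallelic SNP carries an ancestral and derived allele plus the two
flanking bases on the ancestral background. Variants whose ancestral
allele is a purine are reverse complemented (alleles complemented,
flanks swapped and complemented) so classes are written with an
ancestral T or C: T>A, T>C, T>G, C>A, C>G, C>T. C>T (and, for the
CpG-matched ratio, C>A) is split by CpG status — defined solely by a G
immediately 3' of the collapsed ancestral C, since that is the
methylation-prone dinucleotide — and T>C is split by TpG status, because
ancient TpG>CpG calls are enriched for mis-polarized, hypermutable CpG
transitions. Variants with a missing or ambiguous flank are excluded,
mirroring the upstream treatment of unresolved ancestral sequence.

As a proxy for sites attributable to the UV- and alkylation-associated
somatic signatures (which are C>T-dominated in YCN and NCY
trinucleotides), `is_cosmic_proxy_context()` flags C>T variants with a
pyrimidine on either flank so ratio analyses can be repeated without
them.

## Allele-age binning with pseudo-counts

Genealogy-based allele ages come as generous lower/upper bounds, often
an order of magnitude apart. Binning proceeds in two steps:

1. **Boundaries.** For the reference population, one point age per
   variant is drawn uniformly between its bounds (Monte Carlo), and the
   empirical quantiles 0, 1/n, ..., 1 of those point ages become the
   boundaries of n bins (default n = 15) of roughly equal occupancy.
   Because age distributions differ demographically between
   populations, bins cannot be equal-occupancy for all populations at
   once; one reference is chosen and applied everywhere.
2. **Pseudo-counts.** Each variant then contributes fractional mass to
   every bin its interval overlaps, proportional to overlap length
   divided by interval length (a uniform age distribution). An interval
   of (500, 1300) generations over bins (312, 545), (545, 1160),
   (1160, 2970) contributes 45/800 = 0.056, 615/800 = 0.769 and
   140/800 = 0.175.

Numerical choices: a zero-width interval puts unit mass in its
containing bin (last bin closed on the right); mass falling outside the
outermost boundaries is truncated and the remaining weights renormalized
to sum to one, so every retained variant counts exactly once (an
interval entirely outside is flagged and dropped from the table). The
3,000,000-generation upper-bound filter removes ages incompatible with a
plausible human history. Filters older than the binning run first, so
table mass always equals the number of contributing variants.

## Pairwise ratios, CIs, and tests

gBGC favors strong (C/G) over weak (A/T) alleles and so distorts
allele-age distributions differently per mutation class. The analysis
therefore compares only class pairs matched for gBGC: non-CpG C>T vs
non-CpG C>A, CpG C>T vs CpG C>A, C>G vs T>A, and T>C vs T>G. Three of
the four also share mutational opportunity (same ancestral base), and
the four ratios are mathematically independent of one another.

Conditional on the total, the numerator pseudo-count is treated as
binomial: with pseudo-counts $n_1, n_2$, $\hat p = n_1/(n_1+n_2)$ and
$\hat p \pm z\sqrt{\hat p(1-\hat p)/(n_1+n_2)}$ give a CI on the
proportion, transformed to the ratio scale by $p/(1-p)$ and clipped at
zero; $z = 1.96$ for a 95% interval. Interpopulation differences are
tested per bin and ratio with a Pearson chi-square on the
2 x N<sub>pop</sub> table of (possibly fractional) pseudo-counts, no
continuity correction, and Bonferroni correction by bins x ratios
(15 x 4 = 60 in the standard layout). Pseudo-counts enter the statistic
unrounded; bins with a zero class total are flagged and skipped.

## The Poisson parental-age model

Per trio and class, the paternally inherited DNM count is modeled as
Poisson with mean $\beta_p \cdot \mathrm{Fa} + \alpha_p$ (father's age
at conception; intercept at age zero) and the maternal count as
$\beta_m \cdot \mathrm{Mo} + \alpha_m$. Only a fraction of DNMs are
parent-of-origin phased; writing $\phi_i$ for trio $i$'s phased fraction
(estimated as phased/(phased+unphased) pooled across classes and treated
as known), the likelihood takes phased paternal counts as
Poisson($\phi_i \lambda_p$), phased maternal as
Poisson($\phi_i \lambda_m$) and unphased as
Poisson($(1-\phi_i)(\lambda_p + \lambda_m)$). This uses all DNMs and
reduces to the pure Poisson regressions at $\phi \in \{0, 1\}$. A
convenient property: $\phi$ enters the log-likelihood only through
additive constants, so the maximum-likelihood estimates do not depend on
the phasing split — only the information content does.

**Optimization.** Non-negativity of the means over the observed age
range is enforced by parameterizing each parent's mean through its log
values at the youngest and oldest observed age (a positive convex
combination in between). L-BFGS-B with an analytic gradient runs from
two starts (a moment-based linear fit and a flat split), keeping the
better optimum; convergence tolerance is 1e-8 on the log-likelihood.
All-zero counts return the boundary MLE (all parameters zero); designs
without two distinct ages per parent raise an identifiability error.

**Filters.** Trio-level exclusions follow pedigree practice: listed
outlier probands are dropped, as are trios with maternal age above 40
years, where the maternal effect is visibly nonlinear while the model
is linear.

**Uncertainty.** Trios are resampled with replacement and the model
refit (default 500 replicates; 90% percentile intervals). Replicates
are indexed by resample, so two classes bootstrapped with the same seed
are refit on the same resampled trios and preserve their cross-class
correlation — essential when replicates are combined into ratios or
generation-time solutions.

**CpG quintile contrast.** The CpG C>A count is too low (~0.5 per trio)
for a stable per-class fit, so the age dependence of the CpG C>T / CpG
C>A ratio is assessed nonparametrically: trios are ranked by a
parental-age score, and the ratio of total counts in the youngest 20%
is compared with the oldest 20% by a 2 x 2 chi-square. The score is
Fa + Mo by default — the definition of "youngest parents" is genuinely
open, and the symmetric sum is the simplest choice; paternal-only and
maternal-only scores are available.

## Generation-time inversion

If spectrum change were driven solely by reproductive ages, an observed
polymorphism ratio $R$ of two classes would satisfy
$$R = \frac{(\beta_{p1} G_p + \alpha_{p1}) + (\beta_{m1} G_m + \alpha_{m1})}
          {(\beta_{p2} G_p + \alpha_{p2}) + (\beta_{m2} G_m + \alpha_{m2})}.$$
With a fixed paternal/maternal ratio $\gamma = G_p/G_m$ (grid 0.8, 1,
1.1, 1.2) this is linear in $G_m$:
$G_m = [R(\alpha_{p2}+\alpha_{m2}) - (\alpha_{p1}+\alpha_{m1})] /
[(\beta_{p1}\gamma+\beta_{m1}) - R(\beta_{p2}\gamma+\beta_{m2})]$.
Solutions are infeasible when the denominator vanishes, $G_m \le 0$, or
either age leaves the plausible reproductive range, default 13–55 years
(puberty to reproductive cessation; configurable). With freely varying
$(G_p, G_m)$ each ratio defines a constraint line
$a G_p + b G_m = c$ reported for contour plots rather than a point
estimate.

CIs solve the system per paired bootstrap replicate and take percentile
quantiles of the feasible solutions, reporting the infeasible fraction.
Optionally the observed ratio itself is redrawn per replicate from its
binomial sampling distribution (`ratio_counts`), so consistency
comparisons between ratios reflect polymorphism sampling noise as well
as pedigree uncertainty; without it, intervals describe pedigree
uncertainty only, as when the observed ratio is treated as fixed data.

## Power simulations for the hotspot contrast

Maternal C>G mutations concentrate in hotspot regions: 10% of the
genome carries about one-third of the overall maternal age effect (the
summed maternal slopes over classes) yet under 15% of SNPs. The two
strata are modeled region-wise: every per-class parameter scales with
the stratum's genome share, except the maternal C>G slope, which takes
the concentrated share inside hotspots and the conserved remainder
outside. Scaling all of a stratum's parameters leaves its class
fractions unchanged, so the single concentrated slope is what makes the
hotspot C>G fraction more age-sensitive. Note this is a region-level
model: multiplying the slope alone per-SNP would inflate the maternal
mean proportionally and barely change the stratum's age sensitivity.
Consistency requires the genome-wide C>G maternal slope to be at least
the concentrated share of the summed maternal slopes; the default
effect set satisfies this.

Power for two populations with generation times $G_1, G_2$: per
replicate and population, C>G and T>A SNP counts are drawn from two
independent binomials with the expected class fractions at $(G, G)$
(computed over all classes from the effects) and the stratum's SNP
count; a 2 x 2 chi-square is applied and power is the fraction of
replicates with p below the threshold (default 0.001, 10,000
replicates). Because the two types are sampled as independent binomials
rather than one multinomial, the test is very slightly conservative
under the null — the null rejection rate sits at or just below alpha.

## NMF of the 96-context spectrum

The 96 pyrimidine-centered trinucleotide mutation types per (population
x age bin) column, normalized to column sums of one, are factorized by
Kullback–Leibler multiplicative updates (the "brunet" rules). Each rank
runs from multiple random initializations (default 30 for analyses,
fewer in examples); the best run (lowest KL) is kept, and the
cophenetic correlation coefficient is computed from the consensus
matrix of each column's dominant-signature assignment across runs
(average-linkage clustering of one minus consensus). Rank selection
takes the smallest rank maximizing the cophenetic coefficient among
ranks explaining at least 99% of variance
(1 − ‖V − WH‖² / ‖V‖²). The KL objective is provably non-increasing
under the update rules, which the test suite checks iteration by
iteration. Degenerate cases: rank 1 has cophenetic 1 by convention, and
a consensus with all columns always co-clustered is assigned cophenetic
1 rather than an undefined correlation.

## The synthetic-data generators

`simulate_variant_dataset()` draws variants from disjoint age epochs,
each with its own class-fraction vector: a true age uniform within the
epoch, a class from the epoch's fractions, a flanking context uniform
over triplets compatible with the class, and an age interval that
always contains the true age, with lognormal relative half-width
(median 0.5 x the true age, sdlog 0.5) to mimic the order-of-magnitude
uncertainty of genealogy-based ages and to exercise multi-bin weight
spreading. Half the variants are emitted on the purine strand to
exercise collapsing. Presence per population is an independent
Bernoulli draw per epoch.

`simulate_trio_dataset()` draws parental ages from truncated normals in
[10, 60] years and per-class paternal/maternal counts from the linear
Poisson model, phasing each DNM independently with the configured
phased fraction, so phased + unphased totals are conserved exactly.

The default effect set (`default_parental_age_effects()`) encodes, once,
magnitudes resembling the large Icelandic pedigree studies: ~57 DNMs
per trio at parental age 30 with a ~3:1 paternal:maternal ratio; a
strong maternal C>G slope (exceeding one-third of the summed maternal
slopes, as its hotspot concentration requires); ~0.55 CpG C>A DNMs per
trio; and intercept/slope balances that reproduce the reported
directions of ratio change between parental ages 20 and 40 (non-CpG
C>T/C>A down ~8%, CpG C>T/C>A down ~12%, C>G/T>A up ~7%, non-TpG
T>C/T>G down ~6%).

What the generators do *not* emulate — and hence what green tests do
not certify about real data: coalescent genealogies and linked
selection, gBGC dynamics (the ratios are designed to cancel it, the
generator simply omits it), recurrent mutation and mis-polarization,
context-dependent mutation-rate variation beyond class definitions,
population structure in presence patterns, and nonlinear maternal age
effects (handled in real data by the age-40 filter).

## Problem sizes in the test and acceptance runs

The suite exercises: parameter recovery on 10,000 synthetic trios with
a 100-replicate bootstrap; percentile-CI coverage over 200 independent
simulations of 1,000 trios with 100 bootstrap resamples each (coverage
of a percentile interval is a calibration property, so the moderate
per-simulation size is a deliberate choice); 1,000-table chi-square
equivalence and 1,000-replicate type-I calibration; 10,000-replicate
null power; planted-signature NMF on 96 x 45 matrices; and end-to-end
runs with 40,000–150,000 variants across 3–10 age bins. The analysis
drivers under `analysis/` use similar moderate sizes and finish in a
few minutes.

## Known limitations

- The phased-fraction treatment conditions on an estimated $\phi_i$;
  a fully joint model of phasing is out of scope (and does not affect
  the point estimates, only stated uncertainty, given the constancy
  property above).
- The normal-approximation ratio CI degenerates at $\hat p \in \{0,1\}$
  and is flagged rather than replaced by an exact interval.
- Generation-time inversion assumes the pedigree-derived linear effects
  held in the past; the package quantifies incompatibility between
  ratios under that assumption but cannot attribute it to specific
  mutational mechanisms.
- Ages are treated as uniform within their bounds everywhere; posterior
  age distributions are not supported.
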