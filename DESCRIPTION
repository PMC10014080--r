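Package: mutspectra
Title: Temporal and Interpopulation Changes in the Germline Mutation Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize changes in the germline mutation spectrum
    over evolutionary time and between populations from allele-age-annotated
    polymorphisms, and to test whether shifts in generation time can explain
    those changes. Polymorphisms with genealogy-based allele-age intervals are
    classified into strand-collapsed substitution classes (with CpG and TpG
    refinements), spread across allele-age bins as fractional pseudo-counts
    under a uniform age-uncertainty model, and summarized as gBGC-matched
    pairwise mutation ratios with binomial confidence intervals and chi-square
    tests of interpopulation differences. Sex-specific linear parental-age
    effects on de novo mutation counts are fitted to trio data by Poisson
    maximum likelihood with bootstrap uncertainty, and inverted to obtain the
    generation times compatible with observed polymorphism ratios. Also
    includes binomial power simulations for maternal C>G hotspot contrasts,
    non-negative matrix factorization of the 96-context spectrum with
    cophenetic rank selection, and seeded generators of synthetic variant and
    trio datasets with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
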