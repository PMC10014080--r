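#' Mutation class labels under a refinement scheme
#'
#' The six strand-collapsed substitution classes are T>A, T>C, T>G, C>A,
#' C>G, C>T, each pooling a substitution with its reverse complement (e.g.
#' T>C includes A>G). Refinement schemes split hypermutable contexts:
#' `"six"` uses the base classes; `"eight"` splits C>T by CpG status and
#' T>C by TpG status; `"matched"` additionally splits C>A (and keeps C>T)
#' by CpG status so that CpG-matched pairwise ratios can be formed.
#'
#' @param scheme One of `"matched"`, `"eight"`, `"six"`.
#' @return Character vector of class labels, in canonical order.
#' @export
mutation_classes <- function(scheme = c("matched", "eight", "six")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    six = c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"),
    eight = c("C>A", "C>G", "C>T_CpG", "C>T_nonCpG",
              "T>A", "T>C_TpG", "T>C_nonTpG", "T>G"),
    matched = c("C>A_CpG", "C>A_nonCpG", "C>G", "C>T_CpG", "C>T_nonCpG",
                "T>A", "T>C_TpG", "T>C_nonTpG", "T>G")
  )
}

#' Classify polarized variants into strand-collapsed mutation classes
#'
#' Variants whose ancestral allele is a purine (A or G) are reverse
#' complemented -- alleles complemented and the two flanking bases swapped
#' and complemented -- so that every class is represented with an ancestral
#' T or C, matching the conventional T>*/C>* labels. CpG status is defined
#' by a G immediately 3' of the collapsed ancestral C (equivalently a C
#' immediately 5' of a G>A); TpG status by a G immediately 3' of the
#' collapsed ancestral T. Variants with a missing or ambiguous flanking
#' base (anything outside A/C/G/T) are flagged for exclusion (`class` is
#' `NA` and `exclude_reason` says why), mirroring the upstream treatment of
#' sites with unresolved ancestral context.
#'
#' @param variants Data frame with columns `ancestral`, `derived`,
#'   `five_prime`, `three_prime` (single upper-case bases).
#' @param scheme Refinement scheme, see [mutation_classes()].
#' @return The input with added columns: `base_class`, `cpg`, `tpg`
#'   (logicals), `class` (scheme label or `NA`), `context` (collapsed
#'   trinucleotide mutation type, e.g. `"A[C>T]G"`), and `exclude_reason`.
#' @export
classify_variants <- function(variants, scheme = c("matched", "eight", "six")) {
  scheme <- match.arg(scheme)
  anc <- toupper(variants$ancestral)
  der <- toupper(variants$derived)
  fp <- toupper(variants$five_prime)
  tp <- toupper(variants$three_prime)

  bad_allele <- !(anc %in% DNA_BASES) | !(der %in% DNA_BASES) | anc == der
  if (any(bad_allele)) {
    stop_mutspectra("invalid alleles (non-ACGT or ancestral == derived) in ",
                    sum(bad_allele), " rows; reject them when reading")
  }

  flip <- anc %in% c("A", "G")
  anc_c <- ifelse(flip, complement_base(anc), anc)
  der_c <- ifelse(flip, complement_base(der), der)
  fp_c <- ifelse(flip, complement_base(tp), fp)
  tp_c <- ifelse(flip, complement_base(fp), tp)

  ok_ctx <- fp_c %in% DNA_BASES & tp_c %in% DNA_BASES
  base_class <- paste0(anc_c, ">", der_c)
  cpg <- ok_ctx & anc_c == "C" & tp_c == "G"
  tpg <- ok_ctx & anc_c == "T" & tp_c == "G"

  cls <- base_class
  if (scheme %in% c("eight", "matched")) {
    split_cpg <- if (scheme == "matched") c("C>T", "C>A") else "C>T"
    sel <- base_class %in% split_cpg
    cls[sel] <- paste0(base_class[sel], ifelse(cpg[sel], "_CpG", "_nonCpG"))
    sel <- base_class == "T>C"
    cls[sel] <- paste0("T>C", ifelse(tpg[sel], "_TpG", "_nonTpG"))
  }
  cls[!ok_ctx] <- NA_character_

  variants$base_class <- base_class
  variants$cpg <- ifelse(ok_ctx, cpg, NA)
  variants$tpg <- ifelse(ok_ctx, tpg, NA)
  variants$class <- cls
  variants$context <- ifelse(ok_ctx,
                             paste0(fp_c, "[", base_class, "]", tp_c),
                             NA_character_)
  variants$exclude_reason <- ifelse(ok_ctx, NA_character_, "ambiguous_context")
  variants
}

#' Classify a single variant
#'
#' Convenience scalar wrapper around [classify_variants()].
#'
#' @param ancestral,derived,five_prime,three_prime Single bases.
#' @inheritParams classify_variants
#' @return A one-row data frame of class annotations; `class` is `NA` with
#'   `exclude_reason = "ambiguous_context"` when a flank is unresolved.
#' @export
classify_variant <- function(ancestral, derived, five_prime, three_prime,
                             scheme = c("matched", "eight", "six")) {
  classify_variants(
    data.frame(ancestral = ancestral, derived = derived,
               five_prime = five_prime, three_prime = three_prime,
               stringsAsFactors = FALSE),
    scheme = match.arg(scheme)
  )
}

#' Flag C>T variants in pyrimidine-flanked contexts (signature proxies)
#'
#' Somatic signatures SBS7a/b and SBS11 are dominated by C>T mutations in
#' YCN and NCY contexts respectively (Y = pyrimidine, N = any base). As a
#' proxy for sites potentially affected by these processes, C>T variants
#' with a pyrimidine on either flank (in collapsed orientation) are
#' flagged so they can be removed from ratio analyses.
#'
#' @param base_class Character vector of base classes (`"C>T"` etc.), in
#'   collapsed orientation.
#' @param five_prime,three_prime Collapsed-orientation flanking bases.
#' @return Logical vector: `TRUE` iff C>T with a C or T on either flank.
#' @export
is_cosmic_proxy_context <- function(base_class, five_prime, three_prime) {
  base_class == "C>T" &
    (five_prime %in% c("C", "T") | three_prime %in% c("C", "T"))
}

#' Classify variants as shared or non-shared across continental groups
#'
#' A variant is "shared" when both of its alleles are observed in at least
#' one population from every continental group, e.g. segregating in
#' (YRI or LWK) and (CEU or TSI) and (CHB or JPT).
#'
#' @param presence Character vector, one element per variant, of
#'   comma-separated population labels in which the variant segregates.
#' @param groups List of character vectors, one per continental group.
#' @return Character vector `"shared"`/`"non_shared"`.
#' @export
classify_sharing <- function(presence, groups) {
  if (length(groups) == 0L || any(lengths(groups) == 0L)) {
    stop_mutspectra("each continental group must contain at least one population")
  }
  pops <- strsplit(presence, ",", fixed = TRUE)
  vapply(pops, function(p) {
    if (all(vapply(groups, function(g) any(g %in% p), logical(1L))))
      "shared" else "non_shared"
  }, character(1L))
}
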