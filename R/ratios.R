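#' The four gBGC-matched pairwise mutation ratios
#'
#' Each ratio compares two mutation classes matched for the effect of
#' GC-biased gene conversion (both favored, both disfavored, or both
#' neutral), so that differences in the ratio across time or populations
#' reflect the mutation process rather than transmission bias:
#' (1) non-CpG C>T / non-CpG C>A, (2) CpG C>T / CpG C>A, (3) C>G / T>A,
#' (4) T>C / T>G. Numerator/denominator entries are vectors of class
#' labels (in the `"matched"` scheme) whose pseudo-counts are summed.
#'
#' @param tpg_excluded If `TRUE`, ratio 4 uses non-TpG T>C only (TpG sites
#'   are enriched for mis-polarized CpG transitions at old ages).
#' @return Named list of ratio definitions (`numerator`, `denominator`,
#'   `label`).
#' @export
pairwise_ratio_definitions <- function(tpg_excluded = FALSE) {
  tc <- if (tpg_excluded) "T>C_nonTpG" else c("T>C_TpG", "T>C_nonTpG")
  tc_lab <- if (tpg_excluded) "nonTpG T>C/T>G" else "T>C/T>G"
  list(
    nonCpG_CT_CA = list(numerator = "C>T_nonCpG", denominator = "C>A_nonCpG",
                        label = "nonCpG C>T/C>A"),
    CpG_CT_CA = list(numerator = "C>T_CpG", denominator = "C>A_CpG",
                     label = "CpG C>T/C>A"),
    CG_TA = list(numerator = "C>G", denominator = "T>A", label = "C>G/T>A"),
    TC_TG = list(numerator = tc, denominator = "T>G", label = tc_lab)
  )
}

#' Ratio of two pseudo-counts with a binomial-approximation CI
#'
#' Conditional on the total, the count of the first type is treated as
#' binomial; the normal-approximation CI of the proportion
#' `p = n1/(n1+n2)`, `p +/- z*sqrt(p(1-p)/(n1+n2))`, is transformed to the
#' ratio scale via `p/(1-p)` and clipped to `[0, Inf)`.
#'
#' @param n1,n2 Pseudo-counts of the two mutation types (non-negative,
#'   possibly fractional).
#' @param z Standard-normal quantile; 1.96 gives a 95% CI.
#' @return List with `ratio`, `ci_lower`, `ci_upper`, `p_hat`, `n1`, `n2`,
#'   `z`, and `degenerate` (`TRUE` when `p_hat` is 0 or 1 so the normal
#'   approximation collapses).
#' @export
ratio_with_ci <- function(n1, n2, z = 1.96) {
  if (n1 + n2 <= 0) stop_mutspectra("n1 + n2 must be positive")
  if (n2 == 0) stop_mutspectra("ratio undefined: denominator pseudo-count is 0")
  p <- n1 / (n1 + n2)
  se <- sqrt(p * (1 - p) / (n1 + n2))
  pl <- max(0, p - z * se)
  pu <- min(1, p + z * se)
  odds <- function(q) if (q >= 1) Inf else max(0, q / (1 - q))
  list(ratio = n1 / n2, ci_lower = odds(pl), ci_upper = odds(pu),
       p_hat = p, n1 = n1, n2 = n2, z = z,
       degenerate = p %in% c(0, 1))
}

#' Chi-square test of interpopulation differences on pseudo-counts
#'
#' Pearson chi-square on a 2 x N_pop contingency table whose entries are
#' the (possibly fractional) pseudo-counts of the two mutation types in
#' each population, with N_pop - 1 degrees of freedom and no continuity
#' correction.
#'
#' @param table Numeric matrix, 2 rows (mutation types) x N_pop columns.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
interpopulation_chisq <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L) stop_mutspectra("expected a 2 x N_pop table")
  if (any(table < 0)) stop_mutspectra("pseudo-counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop_mutspectra("zero row or column total in contingency table")
  }
  E <- outer(rs, cs) / sum(table)
  stat <- sum((table - E)^2 / E)
  df <- ncol(table) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Bonferroni adjustment over age bins and ratios
#'
#' Multiplies the p-value by the number of tests performed (age bins x
#' pairwise ratios; 15 x 4 = 60 in the standard analysis), capped at 1.
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param n_age_bins,n_ratios Test-grid dimensions.
#' @return Adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, n_age_bins = 15L, n_ratios = 4L) {
  stopifnot(all(p >= 0 & p <= 1))
  pmin(1, p * n_age_bins * n_ratios)
}

#' Partition variants by membership in a genomic region set
#'
#' Regions follow the BED convention (0-based half-open); variant
#' positions are 1-based, so a variant at position `pos` is inside a
#' region `[start, end)` iff `start <= pos - 1 < end`.
#'
#' @param variants Variant data frame with `chrom` and `pos`.
#' @param regions A `GRanges` of regions as returned by [read_regions()]
#'   (1-based closed internally), or `NULL`/empty for no regions.
#' @return List with elements `inside` and `outside` (data frames).
#' @export
stratify_by_regions <- function(variants, regions) {
  if (is.null(regions) || length(regions) == 0L) {
    return(list(inside = variants[0, , drop = FALSE], outside = variants))
  }
  v <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1L)
  )
  hit <- GenomicRanges::countOverlaps(v, regions) > 0
  list(inside = variants[hit, , drop = FALSE],
       outside = variants[!hit, , drop = FALSE])
}

#' Pairwise ratio trajectories with CIs and interpopulation tests
#'
#' For each pairwise ratio and age bin, computes the per-population ratio
#' of pseudo-counts with its binomial-approximation CI, plus a chi-square
#' test of interpopulation differences on the 2 x N_pop table and its
#' Bonferroni-adjusted p-value (bins x ratios tests).
#'
#' @param tables Named list (by population) of pseudo-count matrices from
#'   [build_pseudocount_table()], sharing class rows and bins.
#' @param definitions Ratio definitions, see [pairwise_ratio_definitions()].
#' @param z Normal quantile for the CIs.
#' @return Tidy data frame: population, bin, ratio label, ratio, ci_lower,
#'   ci_upper, n1, n2, p_raw, p_adjusted (test columns repeated across the
#'   populations of a bin; `NA` when a bin has a zero class total).
#' @export
ratio_trajectories <- function(tables, definitions = pairwise_ratio_definitions(),
                               z = 1.96) {
  pops <- names(tables)
  nb <- ncol(tables[[1L]])
  n_tests_bins <- nb
  out <- list()
  for (dname in names(definitions)) {
    def <- definitions[[dname]]
    for (b in seq_len(nb)) {
      n1 <- vapply(tables, function(t) sum(t[def$numerator, b]), numeric(1L))
      n2 <- vapply(tables, function(t) sum(t[def$denominator, b]), numeric(1L))
      ok <- n1 + n2 > 0 & n2 > 0
      p_raw <- NA_real_
      if (all(n1 + n2 > 0) && length(pops) > 1L) {
        tab <- rbind(n1, n2)
        if (all(colSums(tab) > 0) && all(rowSums(tab) > 0)) {
          p_raw <- interpopulation_chisq(tab)$p_value
        }
      }
      for (i in seq_along(pops)) {
        est <- if (ok[i]) ratio_with_ci(n1[i], n2[i], z) else
          list(ratio = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_)
        out[[length(out) + 1L]] <- data.frame(
          population = pops[i], bin = b, ratio_name = dname,
          ratio_label = def$label, ratio = est$ratio,
          ci_lower = est$ci_lower, ci_upper = est$ci_upper,
          n1 = n1[i], n2 = n2[i], p_raw = p_raw,
          p_adjusted = if (is.na(p_raw)) NA_real_ else
            bonferroni_adjust(p_raw, n_tests_bins, length(definitions)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}
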