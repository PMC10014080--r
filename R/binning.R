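#' Remove variants unusable for age-binned spectrum analysis
#'
#' Drops variants whose allele-age upper bound exceeds `max_age`
#' generations (ages incompatible with a plausible human evolutionary
#' history) and, when class annotations are present, variants excluded for
#' ambiguous flanking context.
#'
#' @param variants Variant data frame with `age_lower`, `age_upper`
#'   (generations); optionally a `class` column from [classify_variants()].
#' @param max_age Oldest admissible age upper bound, in generations.
#' @return The filtered data frame.
#' @export
filter_variants <- function(variants, max_age = 3e6) {
  keep <- variants$age_upper <= max_age
  if (!is.null(variants$class)) keep <- keep & !is.na(variants$class)
  variants[keep, , drop = FALSE]
}

#' Determine allele-age bin boundaries from a reference population
#'
#' For each variant a point age is drawn uniformly between its inferred
#' lower and upper age bounds (a Monte Carlo draw that propagates the
#' order-of-magnitude uncertainty of genealogy-based ages), and the bin
#' boundaries are the empirical quantiles 0, 1/n, ..., 1 of the sampled
#' point ages, giving bins of roughly equal occupancy in the reference
#' population. Bins are half-open `[b_i, b_{i+1})` except the last, which
#' is closed.
#'
#' @param variants Variants of the reference population (filtered).
#' @param n_bins Number of bins (default 15).
#' @param seed Integer seed for the Monte Carlo point draws.
#' @param reference_population Label recorded in the result.
#' @return An object of class `"age_binning"`: list with `boundaries`
#'   (length `n_bins + 1`), `n_bins`, `reference_population`, `seed`.
#' @export
determine_bin_boundaries <- function(variants, n_bins = 15L, seed = 1L,
                                     reference_population = "CEU") {
  if (n_bins < 1L) stop_mutspectra("n_bins must be >= 1")
  if (nrow(variants) < n_bins) {
    stop_mutspectra("need at least n_bins variants to place boundaries")
  }
  pts <- with_seed(seed, runif(nrow(variants), variants$age_lower,
                               variants$age_upper))
  b <- unname(quantile(pts, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (n_bins > 1L && any(diff(b) <= 0)) {
    stop_mutspectra("degenerate (tied) bin boundaries")
  }
  structure(
    list(boundaries = b, n_bins = as.integer(n_bins),
         reference_population = reference_population, seed = seed),
    class = "age_binning"
  )
}

#' @export
print.age_binning <- function(x, ...) {
  cat("Allele-age binning:", x$n_bins, "bins on",
      x$reference_population, "point ages\n")
  cat("boundaries (generations):",
      paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Spread a variant's unit mass across age bins
#'
#' Assuming the variant's true age is uniformly distributed on
#' `[age_lower, age_upper]`, the weight in bin `[b_i, b_{i+1})` is the
#' overlap length divided by the interval length `age_upper - age_lower`.
#' A zero-width interval puts unit mass in its containing bin. Mass
#' falling outside the outermost boundaries is truncated and the weights
#' renormalized to sum to 1; an interval entirely outside the binning
#' range returns a zero vector with attribute `outside = TRUE`.
#'
#' @param age_lower,age_upper Age interval in generations.
#' @param binning An `"age_binning"` object (or a numeric boundary vector).
#' @return Numeric weight vector of length `n_bins` summing to 1 (or to 0
#'   for a fully outside interval).
#' @export
assign_bin_weights <- function(age_lower, age_upper, binning) {
  b <- if (inherits(binning, "age_binning")) binning$boundaries else binning
  nb <- length(b) - 1L
  if (age_lower > age_upper) stop_mutspectra("age_lower must be <= age_upper")
  w <- bin_overlap_matrix(age_lower, age_upper, b)[1L, ]
  if (sum(w) == 0) attr(w, "outside") <- TRUE
  w
}

# Overlap-fraction matrix [variants x bins]; rows renormalized to 1 where any
# mass falls inside the binning range. Point ages get unit mass in their bin
# (last bin closed on the right).
bin_overlap_matrix <- function(lower, upper, boundaries) {
  nb <- length(boundaries) - 1L
  n <- length(lower)
  lo <- boundaries[-length(boundaries)]
  hi <- boundaries[-1L]
  W <- matrix(0, n, nb)
  pt <- upper == lower
  if (any(!pt)) {
    l <- lower[!pt]; u <- upper[!pt]
    ov <- pmax(
      outer(u, hi, pmin) - outer(l, lo, pmax),
      0
    )
    W[!pt, ] <- ov / (u - l)
  }
  if (any(pt)) {
    idx <- findInterval(lower[pt], boundaries, rightmost.closed = TRUE,
                        all.inside = FALSE)
    inside <- idx >= 1L & idx <= nb
    W[which(pt)[inside], ] <- 0
    W[cbind(which(pt)[inside], idx[inside])] <- 1
  }
  s <- rowSums(W)
  pos <- s > 0
  W[pos, ] <- W[pos, , drop = FALSE] / s[pos]
  W
}

#' Build a pseudo-count table of mutation classes per age bin
#'
#' Each classified variant contributes its uniform-age bin weights (see
#' [assign_bin_weights()]) to the row of its mutation class, so entry
#' (class, bin) is the expected number of variants of that class arising
#' in that bin. Row/column labels follow the scheme's class order and the
#' binning.
#'
#' @param variants Classified, filtered variant data frame (`class`,
#'   `age_lower`, `age_upper`).
#' @param binning An `"age_binning"` object.
#' @param classes Class labels for rows, default the classes present in a
#'   canonical scheme order (union with any observed labels).
#' @return Matrix `[class x bin]` with attributes `n_variants` (number of
#'   contributing variants, i.e. with mass inside the binning range) and
#'   `n_outside` (variants entirely outside).
#' @export
build_pseudocount_table <- function(variants, binning, classes = NULL) {
  stopifnot(inherits(binning, "age_binning"))
  if (is.null(classes)) {
    known <- c(mutation_classes("matched"), mutation_classes("eight"),
               mutation_classes("six"))
    classes <- unique(c(known[known %in% variants$class],
                        sort(unique(variants$class))))
  }
  nb <- binning$n_bins
  tab <- matrix(0, length(classes), nb,
                dimnames = list(classes, paste0("bin", seq_len(nb))))
  if (nrow(variants) == 0L) {
    attr(tab, "n_variants") <- 0L
    attr(tab, "n_outside") <- 0L
    return(tab)
  }
  W <- bin_overlap_matrix(variants$age_lower, variants$age_upper,
                          binning$boundaries)
  cls <- factor(variants$class, levels = classes)
  if (anyNA(cls)) stop_mutspectra("variants contain classes not in 'classes'")
  agg <- rowsum(W, cls, reorder = FALSE)
  tab[rownames(agg), ] <- agg
  attr(tab, "n_variants") <- sum(rowSums(W) > 0)
  attr(tab, "n_outside") <- sum(rowSums(W) == 0)
  tab
}
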