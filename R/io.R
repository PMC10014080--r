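#' Read a variant table (Relate-style per-SNP dialect)
#'
#' Tab-separated with header; required columns: chrom, pos, ancestral,
#' derived, five_prime, three_prime, age_lower, age_upper, populations
#' (comma-separated labels). Rows with non-ACGT ancestral/derived alleles
#' or with ancestral equal to derived are rejected and counted; rows with
#' unparseable or inverted age bounds raise an error.
#'
#' @param path File path.
#' @return Validated variant data frame; attribute `n_rejected` counts
#'   dropped rows.
#' @export
read_variant_table <- function(path) {
  required <- c("chrom", "pos", "ancestral", "derived", "five_prime",
                "three_prime", "age_lower", "age_upper", "populations")
  d <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  colClasses = "character", check.names = FALSE,
                  stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop_mutspectra("missing required columns: ", paste(miss, collapse = ", "))
  }
  d$pos <- as.integer(d$pos)
  d$age_lower <- suppressWarnings(as.numeric(d$age_lower))
  d$age_upper <- suppressWarnings(as.numeric(d$age_upper))
  if (anyNA(d$age_lower) || anyNA(d$age_upper)) {
    stop_mutspectra("unparseable allele ages")
  }
  if (any(d$age_lower > d$age_upper)) {
    stop_mutspectra("rows with age_lower > age_upper")
  }
  if (any(d$age_lower < 0)) stop_mutspectra("negative allele ages")
  ok <- d$ancestral %in% DNA_BASES & d$derived %in% DNA_BASES &
    d$ancestral != d$derived
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    message("read_variant_table: rejected ", n_rejected,
            " rows with invalid alleles")
  }
  out <- d[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a variant table
#'
#' @param variants Variant data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trio DNM table
#'
#' Long-format TSV: trio_id, father_age, mother_age, class,
#' phased_paternal, phased_maternal, unphased.
#'
#' @param path File path.
#' @return Trio data frame.
#' @export
read_trio_table <- function(path) {
  required <- c("trio_id", "father_age", "mother_age", "class",
                "phased_paternal", "phased_maternal", "unphased")
  d <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop_mutspectra("missing required columns: ", paste(miss, collapse = ", "))
  }
  cnt <- c("phased_paternal", "phased_maternal", "unphased")
  if (any(unlist(d[cnt]) < 0) || any(unlist(d[cnt]) %% 1 != 0)) {
    stop_mutspectra("DNM counts must be non-negative integers")
  }
  if (any(d$father_age <= 0) || any(d$mother_age <= 0)) {
    stop_mutspectra("parental ages must be positive")
  }
  d
}

#' Write a trio DNM table
#'
#' @param trios Trio data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_trio_table <- function(trios, path) {
  write.table(trios, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED region file into merged, sorted intervals
#'
#' BED is 0-based half-open; internally intervals are represented as a
#' 1-based closed `GRanges` (`start+1 .. end`), sorted and with
#' overlapping or book-ended intervals merged.
#'
#' @param path BED file path (3+ columns, no header).
#' @return A `GRanges` (empty for an empty file).
#' @export
read_regions <- function(path) {
  if (file.size(path) == 0L) return(GenomicRanges::GRanges())
  d <- read.table(path, header = FALSE, sep = "\t", quote = "",
                  stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop_mutspectra("BED needs at least 3 columns")
  start0 <- as.numeric(d[[2L]]); end0 <- as.numeric(d[[3L]])
  if (any(start0 >= end0)) stop_mutspectra("malformed BED interval: start >= end")
  chrom <- as.character(d[[1L]])
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = sort(unique(chrom))),
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
  GenomicRanges::reduce(gr)  # reduce also sorts
}

#' Read a COSMIC-style signature loading table
#'
#' Expects a `Type` column with labels like `"A[C>A]A"` and one numeric
#' column per signature; all 96 trinucleotide mutation types must be
#' present. Loadings are returned in the canonical context order.
#'
#' @param path File path (TSV).
#' @return Numeric matrix 96 x n_signatures, rownames the context
#'   labels.
#' @export
read_cosmic_loadings <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  stringsAsFactors = FALSE, check.names = FALSE)
  type_col <- intersect(c("Type", "type", "MutationType"), names(d))[1L]
  if (is.na(type_col)) stop_mutspectra("no Type column found")
  ctx <- trinucleotide_contexts()
  miss <- setdiff(ctx, d[[type_col]])
  if (length(miss)) {
    stop_mutspectra("missing contexts, e.g. ", miss[1L])
  }
  m <- as.matrix(d[match(ctx, d[[type_col]]),
                   setdiff(names(d), type_col), drop = FALSE])
  rownames(m) <- ctx
  storage.mode(m) <- "double"
  m
}

#' Share of a signature's loading mass in a context subset
#'
#' Computes the fraction of a signature's total loading carried by
#' contexts of a base class with a pyrimidine flank: `"YCN"` selects
#' contexts with a C or T immediately 5' of the mutated base, `"NCY"`
#' those with a C or T immediately 3'.
#'
#' @param loadings Matrix from [read_cosmic_loadings()].
#' @param signature Signature column name.
#' @param flank `"YCN"` or `"NCY"`.
#' @param base_class Central substitution class (default `"C>T"`).
#' @return Fraction in `[0, 1]`.
#' @export
cosmic_context_share <- function(loadings, signature,
                                 flank = c("YCN", "NCY"),
                                 base_class = "C>T") {
  flank <- match.arg(flank)
  ctx <- rownames(loadings)
  fp <- substr(ctx, 1L, 1L)
  tp <- substr(ctx, nchar(ctx), nchar(ctx))
  cls <- substr(ctx, 3L, 5L)
  sel <- cls == base_class &
    (if (flank == "YCN") fp %in% c("C", "T") else tp %in% c("C", "T"))
  v <- loadings[, signature]
  sum(v[sel]) / sum(v)
}

#' Write a pseudo-count table as TSV
#'
#' Matrix layout matching the per-time-window counts source-data style:
#' one row per mutation class, one column per age bin.
#'
#' @param table Matrix from [build_pseudocount_table()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_pseudocount_table <- function(table, path) {
  d <- data.frame(class = rownames(table), as.data.frame(unclass(table)),
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pseudo-count table written by [write_pseudocount_table()]
#'
#' @param path File path.
#' @return Numeric matrix `[class x bin]`.
#' @export
read_pseudocount_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read a spectrum scenario from a YAML configuration file
#'
#' Expected structure: top-level keys `n_variants`, `seed`, optional
#' `age_interval` (`meanlog`, `sdlog`), `populations` (label: presence
#' probability), and `epochs` (list of `age_start`, `age_end`,
#' `class_fractions` mappings).
#'
#' @param path YAML file path.
#' @return A [spectrum_scenario()].
#' @export
read_spectrum_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  epochs <- lapply(cfg$epochs, function(e) {
    list(age_start = e$age_start, age_end = e$age_end,
         class_fractions = unlist(e$class_fractions))
  })
  spectrum_scenario(
    epochs = epochs,
    n_variants = cfg$n_variants,
    populations = cfg$populations %||% list(CEU = 1.0),
    age_interval = cfg$age_interval %||% list(meanlog = log(0.5), sdlog = 0.5),
    seed = cfg$seed %||% 1L
  )
}

#' Write a run manifest
#'
#' Records inputs, seeds and parameters of an analysis stage as
#' key-value lines so a run can be reproduced bit-identically.
#'
#' @param path Destination path.
#' @param ... Named scalar entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  kv <- list(...)
  stopifnot(length(kv) == 0L || !is.null(names(kv)))
  lines <- c(paste0("package_version\t",
                    as.character(utils::packageVersion("mutspectra"))),
             paste0(names(kv), "\t",
                    vapply(kv, function(x) paste(format(x), collapse = ","),
                           character(1L))))
  writeLines(lines, path)
  invisible(path)
}
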