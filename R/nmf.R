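#' The 96 pyrimidine-centered trinucleotide mutation types
#'
#' COSMIC-style labels `"A[C>A]A"` ... `"T[T>G]T"`: 6 base substitution
#' classes (ancestral pyrimidine) x 4 five-prime x 4 three-prime flanks.
#'
#' @return Character vector of length 96, sorted by class then flanks.
#' @export
trinucleotide_contexts <- function() {
  cls <- mutation_classes("six")
  out <- character(0)
  for (cl in cls) {
    for (fp in DNA_BASES) {
      for (tp in DNA_BASES) {
        out <- c(out, paste0(fp, "[", cl, "]", tp))
      }
    }
  }
  out
}

#' Build the normalized 96-context matrix over age bins and populations
#'
#' Accumulates each variant's uniform-age bin weights into the row of its
#' collapsed trinucleotide mutation type, one column per (population,
#' age bin), then divides each column by its total pseudo-count so
#' columns are per-bin mutation-type fractions summing to 1. With 15 bins
#' and 3 populations the matrix is 96 x 45.
#'
#' @param variants_by_population Named list (by population) of classified,
#'   filtered variant data frames (needing `context`, `age_lower`,
#'   `age_upper`).
#' @param binning An `"age_binning"` object.
#' @return Matrix 96 x (bins * populations) with column labels
#'   `"POP.bin<k>"`; attribute `column_totals` holds the per-column
#'   pseudo-counts used for normalization.
#' @export
build_context_matrix <- function(variants_by_population, binning) {
  stopifnot(inherits(binning, "age_binning"))
  ctx <- trinucleotide_contexts()
  cols <- list()
  for (pop in names(variants_by_population)) {
    v <- variants_by_population[[pop]]
    if (anyNA(v$context)) {
      stop_mutspectra("variants with missing context in population ", pop)
    }
    W <- bin_overlap_matrix(v$age_lower, v$age_upper, binning$boundaries)
    f <- factor(v$context, levels = ctx)
    if (anyNA(f)) stop_mutspectra("unknown trinucleotide context label")
    M <- matrix(0, length(ctx), binning$n_bins, dimnames = list(ctx, NULL))
    agg <- rowsum(W, f, reorder = FALSE)
    M[rownames(agg), ] <- agg
    colnames(M) <- paste0(pop, ".bin", seq_len(binning$n_bins))
    cols[[pop]] <- M
  }
  V <- do.call(cbind, cols)
  tot <- colSums(V)
  if (any(tot == 0)) {
    stop_mutspectra("age bin(s) with zero pseudo-counts: ",
                    paste(colnames(V)[tot == 0], collapse = ", "))
  }
  V <- sweep(V, 2L, tot, "/")
  attr(V, "column_totals") <- tot
  V
}

# KL divergence D(V || WH) up to terms constant in W, H
kl_div <- function(V, WH) {
  eps <- .Machine$double.eps
  sum(ifelse(V == 0, 0, V * log(V / pmax(WH, eps))) - V + WH)
}

# one multiplicative-update KL-NMF run
nmf_run <- function(V, rank, max_iter, tol) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(runif(rank * m, 0.1, 1), rank, m)
  eps <- .Machine$double.eps
  obj <- kl_div(V, W %*% H)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, eps)
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    WH <- pmax(W %*% H, eps)
    W <- W * ((V / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = n)
    if (it %% 10L == 0L) {
      new_obj <- kl_div(V, W %*% H)
      if (abs(obj - new_obj) < tol * (abs(obj) + 1e-12)) {
        obj <- new_obj; converged <- TRUE; break
      }
      obj <- new_obj
    }
  }
  # scale signatures to column sums 1, compensating in exposures
  s <- pmax(colSums(W), eps)
  W <- sweep(W, 2L, s, "/")
  H <- H * s
  list(W = W, H = H, kl = kl_div(V, W %*% H), converged = converged)
}

#' Non-negative matrix factorization by KL multiplicative updates
#'
#' Factorizes the non-negative context matrix as `V ~ W H` with the
#' Kullback-Leibler multiplicative update rules ("brunet" algorithm),
#' restarted from `n_runs` random initializations. The best run (lowest
#' KL divergence) is returned; the cophenetic correlation coefficient is
#' computed from the consensus matrix of the columns' dominant-signature
#' assignments across runs (average-linkage clustering of 1 - consensus).
#'
#' @param V Non-negative matrix (contexts x samples).
#' @param rank Factorization rank K.
#' @param n_runs Random restarts used for both the best fit and the
#'   consensus diagnostic (default 30).
#' @param seed Integer seed.
#' @param max_iter,tol Update-iteration budget and relative objective
#'   tolerance per run.
#' @return Object of class `"nmf_result"`: `signatures` (96 x K, columns
#'   sum to 1), `exposures` (K x samples), `kl`, `variance_explained`
#'   (1 - ||V - WH||^2 / ||V||^2), `cophenetic`, `converged`.
#' @export
nmf_factorize <- function(V, rank, n_runs = 30L, seed = 1L,
                          max_iter = 2000L, tol = 1e-9) {
  if (rank < 1L) stop_mutspectra("rank must be >= 1")
  if (n_runs < 1L) stop_mutspectra("n_runs must be >= 1")
  if (any(V < 0)) stop_mutspectra("matrix must be non-negative")
  m <- ncol(V)
  with_seed(seed, {
    runs <- lapply(seq_len(n_runs), function(i) nmf_run(V, rank, max_iter, tol))
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1L), "kl"))]]
    coph <- NA_real_
    if (m > 2L && rank > 1L) {
      consensus <- matrix(0, m, m)
      for (r in runs) {
        assign <- apply(r$H, 2L, which.max)
        consensus <- consensus + outer(assign, assign, "==")
      }
      consensus <- consensus / n_runs
      d <- as.dist(1 - consensus)
      if (max(d) < 1e-12) {
        coph <- 1.0  # identical clustering in every run
      } else {
        hc <- hclust(d, method = "average")
        coph <- suppressWarnings(cor(d, cophenetic(hc)))
        if (is.na(coph)) coph <- 1.0
      }
    } else if (rank == 1L) {
      coph <- 1.0
    }
    rss <- sum((V - best$W %*% best$H)^2)
    structure(
      list(signatures = best$W, exposures = best$H, kl = best$kl,
           variance_explained = 1 - rss / sum(V^2),
           cophenetic = coph, rank = rank, converged = best$converged),
      class = "nmf_result"
    )
  })
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("NMF rank %d: KL = %.4g, evar = %.4f, cophenetic = %.4f\n",
              x$rank, x$kl, x$variance_explained, x$cophenetic))
  invisible(x)
}

#' Select the factorization rank by cophenetic correlation
#'
#' Among candidate ranks whose best factorization explains at least
#' `evar_threshold` of the variance, returns the smallest rank
#' maximizing the cophenetic correlation coefficient (with a threshold
#' of 0 this is the cophenetic argmax alone).
#'
#' @param V Non-negative matrix.
#' @param ranks Candidate ranks (default 2:6).
#' @param n_runs,seed,max_iter,tol Passed to [nmf_factorize()].
#' @param evar_threshold Minimum variance explained (default 0.99).
#' @return Selected rank (integer); attribute `diagnostics` holds the
#'   per-rank evar and cophenetic values.
#' @export
select_rank <- function(V, ranks = 2:6, n_runs = 30L, seed = 1L,
                        max_iter = 2000L, tol = 1e-9,
                        evar_threshold = 0.99) {
  if (length(ranks) == 0L) stop_mutspectra("ranks must be non-empty")
  fits <- lapply(seq_along(ranks), function(i) {
    nmf_factorize(V, ranks[i], n_runs, seed + i, max_iter, tol)
  })
  evar <- vapply(fits, `[[`, numeric(1L), "variance_explained")
  coph <- vapply(fits, `[[`, numeric(1L), "cophenetic")
  eligible <- evar >= evar_threshold
  if (!any(eligible)) eligible <- rep(TRUE, length(ranks))
  cand <- which(eligible)
  best <- cand[which.max(coph[cand])]
  structure(as.integer(ranks[best]),
            diagnostics = data.frame(rank = ranks, variance_explained = evar,
                                     cophenetic = coph))
}

#' Cosine similarity matching of recovered to reference signatures
#'
#' @param recovered,reference Matrices with signatures in columns.
#' @return Data frame with, per reference signature, the best-matching
#'   recovered column and the cosine similarity (greedy one-to-one
#'   assignment, best matches first).
#' @export
match_signatures <- function(recovered, reference) {
  cs <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  S <- outer(seq_len(ncol(reference)), seq_len(ncol(recovered)),
             Vectorize(function(i, j) cs(reference[, i], recovered[, j])))
  out <- data.frame(reference = seq_len(ncol(reference)),
                    recovered = NA_integer_, cosine = NA_real_)
  taken <- logical(ncol(recovered))
  for (k in seq_len(min(ncol(reference), ncol(recovered)))) {
    S2 <- S
    S2[, taken] <- -Inf
    S2[!is.na(out$cosine), ] <- -Inf
    ij <- arrayInd(which.max(S2), dim(S2))
    out$recovered[ij[1L]] <- ij[2L]
    out$cosine[ij[1L]] <- S[ij[1L], ij[2L]]
    taken[ij[2L]] <- TRUE
  }
  out
}
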