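#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed, evaluates `expr`, and restores the caller's RNG
#' state afterwards, so seeded package functions do not disturb the global
#' random number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

#' Complement DNA bases
#'
#' @param x Character vector of single bases (A/C/G/T); anything else maps
#'   to `NA`.
#' @return Character vector of complements.
#' @export
complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mutspectra <- function(...) stop(..., call. = FALSE)
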