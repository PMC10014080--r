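#' Generation time compatible with an observed polymorphism ratio
#'
#' Under the hypothesis that changes in the polymorphism ratio of two
#' mutation classes are driven solely by shifts in mean reproductive
#' ages, the maternal generation time solves the linear equation obtained
#' by setting the predicted DNM ratio at `(Gp, Gm) = (gamma * Gm, Gm)`
#' equal to the observed pseudo-count ratio `R`:
#' `Gm = (R * (alpha_p2 + alpha_m2) - (alpha_p1 + alpha_m1)) /
#'       ((beta_p1 * gamma + beta_m1) - R * (beta_p2 * gamma + beta_m2))`.
#' The solution is infeasible when the denominator vanishes, when
#' `Gm <= 0`, or when either parental age falls outside the plausible
#' reproductive range.
#'
#' @param R Observed ratio of pseudo-counts (numerator class over
#'   denominator class) in an age bin.
#' @param effect1,effect2 [parental_age_effect()]s of the numerator and
#'   denominator classes.
#' @param gamma Assumed ratio of paternal to maternal generation time
#'   (`Gp / Gm`).
#' @param plausible_range Years bounding feasible generation times,
#'   default `c(13, 55)` (between puberty and reproductive cessation).
#' @return Object of class `"generation_time_solution"`: list with `Gm`,
#'   `Gp`, `gamma`, `feasible`, and `reason` (`NA` when feasible).
#' @export
solve_generation_time <- function(R, effect1, effect2, gamma = 1,
                                  plausible_range = c(13, 55)) {
  if (R <= 0) stop_mutspectra("R must be positive")
  if (gamma <= 0) stop_mutspectra("gamma must be positive")
  a1 <- effect1$alpha_p + effect1$alpha_m
  a2 <- effect2$alpha_p + effect2$alpha_m
  num <- R * a2 - a1
  den <- (effect1$beta_p * gamma + effect1$beta_m) -
    R * (effect2$beta_p * gamma + effect2$beta_m)
  if (abs(den) < 1e-12) {
    return(structure(list(Gm = NA_real_, Gp = NA_real_, gamma = gamma,
                          feasible = FALSE, reason = "no_solution"),
                     class = "generation_time_solution"))
  }
  Gm <- num / den
  Gp <- gamma * Gm
  reason <- NA_character_
  feasible <- TRUE
  if (Gm <= 0) {
    feasible <- FALSE; reason <- "nonpositive"
  } else if (Gm < plausible_range[1L] || Gm > plausible_range[2L] ||
             Gp < plausible_range[1L] || Gp > plausible_range[2L]) {
    feasible <- FALSE; reason <- "outside_plausible_range"
  }
  structure(list(Gm = Gm, Gp = Gp, gamma = gamma, feasible = feasible,
                 reason = reason),
            class = "generation_time_solution")
}

#' @export
print.generation_time_solution <- function(x, ...) {
  cat(sprintf("Gm = %.2f yr, Gp = %.2f yr (gamma = %.2f)%s\n",
              x$Gm, x$Gp, x$gamma,
              if (isTRUE(x$feasible)) "" else
                paste0(" [infeasible: ", x$reason, "]")))
  invisible(x)
}

#' Bootstrap confidence interval of the inferred generation time
#'
#' Solves the generation-time equation with the effect estimates from
#' each pair of bootstrap replicates (paired by resample index, so both
#' classes are refit on the same resampled trios) and summarizes the
#' feasible solutions by percentile quantiles.
#'
#' @param R Observed ratio.
#' @param boot1,boot2 [bootstrap_effects()] results for the numerator
#'   and denominator classes, drawn with the same seed and `n_reps`.
#' @param gamma Paternal-to-maternal generation time ratio.
#' @param level CI coverage (default 0.90).
#' @param plausible_range Feasibility bounds in years.
#' @param ratio_counts Optional `c(n1, n2)` pseudo-counts behind `R`.
#'   When given, each replicate also redraws the observed ratio from
#'   its binomial sampling distribution (normal approximation on the
#'   proportion scale, centered on `R`, with the total count setting
#'   the noise scale), so the interval reflects both the pedigree and
#'   the polymorphism sampling uncertainty.
#' @param seed Seed for the ratio redraws (only used with
#'   `ratio_counts`).
#' @return List with `ci_lower`, `ci_upper` (years, for `Gm`),
#'   `infeasible_fraction`, and `solutions` (per-replicate `Gm`, `NA`
#'   when infeasible or failed).
#' @export
bootstrap_generation_time <- function(R, boot1, boot2, gamma = 1,
                                      level = 0.90,
                                      plausible_range = c(13, 55),
                                      ratio_counts = NULL, seed = 1L) {
  stopifnot(inherits(boot1, "bootstrap_set"), inherits(boot2, "bootstrap_set"))
  n_reps <- length(boot1$replicates)
  if (n_reps != length(boot2$replicates)) {
    stop_mutspectra("replicate sets must be paired (equal n_reps)")
  }
  Rs <- rep(R, n_reps)
  if (!is.null(ratio_counts)) {
    n_tot <- sum(ratio_counts)
    p <- R / (1 + R)
    ps <- with_seed(seed, rnorm(n_reps, p, sqrt(p * (1 - p) / n_tot)))
    ps <- pmin(pmax(ps, 1e-12), 1 - 1e-12)
    Rs <- ps / (1 - ps)
  }
  gm <- mapply(function(e1, e2, r) {
    if (is.null(e1) || is.null(e2)) return(NA_real_)
    s <- solve_generation_time(r, e1, e2, gamma, plausible_range)
    if (isTRUE(s$feasible)) s$Gm else NA_real_
  }, boot1$replicates, boot2$replicates, Rs)
  ok <- !is.na(gm)
  if (!any(ok)) stop_mutspectra("all bootstrap replicates infeasible")
  a <- (1 - level) / 2
  ci <- quantile(gm[ok], c(a, 1 - a), names = FALSE)
  list(ci_lower = ci[1L], ci_upper = ci[2L],
       infeasible_fraction = mean(!ok), solutions = gm)
}

#' Linear (Gp, Gm) constraint implied by an observed ratio
#'
#' When paternal and maternal generation times vary freely, the
#' combinations `(Gp, Gm)` reproducing an observed ratio `R` lie on the
#' line `a * Gp + b * Gm = c` with `a = beta_p1 - R * beta_p2`,
#' `b = beta_m1 - R * beta_m2`,
#' `c = R * (alpha_p2 + alpha_m2) - (alpha_p1 + alpha_m1)`.
#'
#' @inheritParams solve_generation_time
#' @return List with `a`, `b`, `c` and `degenerate`: `"plane"` when all
#'   coefficients vanish (every (Gp, Gm) solves), `"inconsistent"` when
#'   `a = b = 0` but `c != 0`, else `NA`.
#' @export
constraint_line <- function(R, effect1, effect2) {
  if (R <= 0) stop_mutspectra("R must be positive")
  a <- effect1$beta_p - R * effect2$beta_p
  b <- effect1$beta_m - R * effect2$beta_m
  cc <- R * (effect2$alpha_p + effect2$alpha_m) -
    (effect1$alpha_p + effect1$alpha_m)
  degenerate <- NA_character_
  if (abs(a) < 1e-12 && abs(b) < 1e-12) {
    degenerate <- if (abs(cc) < 1e-12) "plane" else "inconsistent"
  }
  list(a = a, b = b, c = cc, degenerate = degenerate)
}
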