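#' Sex-specific linear parental-age effect for one mutation class
#'
#' The expected number of de novo mutations (DNMs) of a class inherited
#' from a parent is modeled as linear in that parent's age at conception:
#' `beta_p * father_age + alpha_p` paternally and
#' `beta_m * mother_age + alpha_m` maternally, with intercepts taken at
#' age zero.
#'
#' @param class Mutation class label.
#' @param alpha_p Expected paternal DNMs at age 0.
#' @param beta_p Paternal DNMs per year of father's age.
#' @param alpha_m,beta_m Maternal analogues.
#' @param age_range Ages (years) over which predicted means must be
#'   non-negative: a length-2 vector applied to both parents, or a list
#'   with elements `paternal` and `maternal` (fitted effects only
#'   guarantee non-negativity over the observed age ranges).
#' @return Object of class `"parental_age_effect"`.
#' @export
parental_age_effect <- function(class, alpha_p, beta_p, alpha_m, beta_m,
                                age_range = c(10, 60)) {
  eff <- structure(
    list(class = class, alpha_p = unname(alpha_p), beta_p = unname(beta_p),
         alpha_m = unname(alpha_m), beta_m = unname(beta_m)),
    class = "parental_age_effect"
  )
  rng <- if (is.list(age_range)) age_range else
    list(paternal = age_range, maternal = age_range)
  tol <- -1e-9
  if (any(eff$beta_p * rng$paternal + eff$alpha_p < tol) ||
      any(eff$beta_m * rng$maternal + eff$alpha_m < tol)) {
    stop_mutspectra("predicted means are negative within the parental ",
                    "age range")
  }
  eff
}

#' @export
print.parental_age_effect <- function(x, ...) {
  cat(sprintf("%s: paternal %.4g + %.4g/yr, maternal %.4g + %.4g/yr\n",
              x$class, x$alpha_p, x$beta_p, x$alpha_m, x$beta_m))
  invisible(x)
}

predict_parent_means <- function(effect, father_age, mother_age) {
  list(paternal = effect$beta_p * father_age + effect$alpha_p,
       maternal = effect$beta_m * mother_age + effect$alpha_m)
}

#' Expected total DNM count of a class at given parental ages
#'
#' @param effect A [parental_age_effect()].
#' @param father_age,mother_age Ages at conception (years).
#' @return Expected paternal + maternal count.
#' @export
predict_class_mean <- function(effect, father_age, mother_age) {
  mu <- predict_parent_means(effect, father_age, mother_age)
  mu$paternal + mu$maternal
}

#' Predicted pairwise ratio of two mutation classes at given parental ages
#'
#' Ratio of the expected total (paternal + maternal) DNM counts of two
#' classes when fathers reproduce at age `Gp` and mothers at `Gm`.
#'
#' @param effect1,effect2 Numerator and denominator
#'   [parental_age_effect()]s.
#' @param Gp,Gm Paternal and maternal ages (years).
#' @return Positive real ratio.
#' @export
predict_ratio <- function(effect1, effect2, Gp, Gm) {
  num <- predict_class_mean(effect1, Gp, Gm)
  den <- predict_class_mean(effect2, Gp, Gm)
  if (any(den <= 0)) stop_mutspectra("non-positive denominator mean")
  num / den
}

#' Expected DNM class fractions at a common parental age
#'
#' Fractions of each mutation class among all de novo single-nucleotide
#' mutations when both parents reproduce at age `G` (or at `Gp`/`Gm`),
#' computed from the fitted linear effects of every class.
#'
#' @param effects Named list of [parental_age_effect()]s covering all
#'   classes.
#' @param G Common parental age; overridden by `Gp`/`Gm` if given.
#' @param Gp,Gm Optional sex-specific ages.
#' @return Named numeric vector of fractions summing to 1.
#' @export
expected_class_fractions <- function(effects, G, Gp = G, Gm = G) {
  mu <- vapply(effects, predict_class_mean, numeric(1L),
               father_age = Gp, mother_age = Gm)
  if (any(mu < 0)) stop_mutspectra("negative expected class mean")
  mu / sum(mu)
}

#' Realistic per-class parental-age effects
#'
#' A set of sex-specific linear effects for the nine `"matched"` classes
#' with magnitudes chosen to resemble large Icelandic pedigree studies: a
#' strong overall paternal age effect (roughly 3-4x the maternal one), a
#' disproportionately strong maternal age effect on C>G (its maternal
#' slope exceeds one-third of the summed maternal slopes, as required
#' for its reported concentration in hotspot regions), and a low CpG
#' C>A rate (about 0.5 DNMs per trio). The relative intercept/slope
#' balance also reproduces the reported directions of the pairwise-ratio
#' age dependence: non-CpG C>T/C>A, CpG C>T/C>A and T>C/T>G decrease
#' between parental ages 20 and 40 while C>G/T>A increases. Used as defaults for the synthetic
#' trio generator and for power simulations.
#'
#' @return Named list of [parental_age_effect()]s.
#' @export
default_parental_age_effects <- function() {
  p <- list(
    "C>A_CpG"    = c(0.05, 0.013, 0.02, 0.004),
    "C>A_nonCpG" = c(0.80, 0.100, 0.30, 0.020),
    "C>G"        = c(0.70, 0.120, 0.00, 0.150),
    "C>T_CpG"    = c(2.20, 0.200, 0.80, 0.040),
    "C>T_nonCpG" = c(2.20, 0.140, 0.80, 0.040),
    "T>A"        = c(0.60, 0.100, 0.15, 0.020),
    "T>C_TpG"    = c(0.40, 0.080, 0.12, 0.015),
    "T>C_nonTpG" = c(1.60, 0.280, 0.50, 0.050),
    "T>G"        = c(0.30, 0.105, 0.08, 0.025)
  )
  out <- lapply(names(p), function(cl) {
    v <- p[[cl]]
    parental_age_effect(cl, alpha_p = v[1L], beta_p = v[2L],
                        alpha_m = v[3L], beta_m = v[4L])
  })
  names(out) <- names(p)
  out
}
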