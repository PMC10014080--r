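#' Define a synthetic trio DNM scenario
#'
#' @param n_trios Number of trios.
#' @param effects Named list of [parental_age_effect()]s, one per
#'   mutation class to simulate.
#' @param father_age,mother_age Lists with `mean` and `sd` (years) of the
#'   parental age samplers; draws are truncated to `[10, 60]`.
#' @param phased_fraction Probability that a DNM is parent-of-origin
#'   assigned; the remainder are reported as unphased.
#' @param seed Integer seed.
#' @return Object of class `"trio_scenario"`.
#' @export
trio_scenario <- function(n_trios, effects = default_parental_age_effects(),
                          father_age = list(mean = 30, sd = 6),
                          mother_age = list(mean = 28, sd = 5),
                          phased_fraction = 0.45, seed = 1L) {
  if (n_trios < 1L) stop_mutspectra("n_trios must be positive")
  if (phased_fraction < 0 || phased_fraction > 1) {
    stop_mutspectra("phased_fraction must be in [0, 1]")
  }
  stopifnot(length(effects) >= 1L,
            all(vapply(effects, inherits, logical(1L), "parental_age_effect")))
  structure(
    list(n_trios = as.integer(n_trios), effects = effects,
         father_age = father_age, mother_age = mother_age,
         phased_fraction = phased_fraction, seed = seed),
    class = "trio_scenario"
  )
}

#' Simulate a trio DNM table under Poisson parental-age effects
#'
#' Per trio and mutation class, the paternally and maternally inherited
#' DNM counts are independent Poisson draws with means linear in the
#' father's and mother's age at conception. Each DNM is independently
#' parent-of-origin phased with probability `phased_fraction`; unphased
#' paternal and maternal DNMs are pooled into the `unphased` column, so
#' `phased_paternal + phased_maternal + unphased` is the trio's total for
#' the class.
#'
#' @param scenario A [trio_scenario()].
#' @return Long-format data frame: trio_id, father_age, mother_age,
#'   class, phased_paternal, phased_maternal, unphased.
#' @export
simulate_trio_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "trio_scenario"))
  with_seed(scenario$seed, {
    n <- scenario$n_trios
    fa <- pmin(60, pmax(10, rnorm(n, scenario$father_age$mean,
                                  scenario$father_age$sd)))
    mo <- pmin(60, pmax(10, rnorm(n, scenario$mother_age$mean,
                                  scenario$mother_age$sd)))
    phi <- scenario$phased_fraction
    rows <- lapply(names(scenario$effects), function(cl) {
      eff <- scenario$effects[[cl]]
      lam_p <- eff$beta_p * fa + eff$alpha_p
      lam_m <- eff$beta_m * mo + eff$alpha_m
      if (any(lam_p < 0) || any(lam_m < 0)) {
        stop_mutspectra("negative predicted mean for class ", cl,
                        " at a sampled age")
      }
      np <- rpois(n, lam_p)
      nm <- rpois(n, lam_m)
      pp <- rbinom(n, np, phi)
      pm <- rbinom(n, nm, phi)
      data.frame(
        trio_id = sprintf("trio%05d", seq_len(n)),
        father_age = fa, mother_age = mo, class = cl,
        phased_paternal = pp, phased_maternal = pm,
        unphased = (np - pp) + (nm - pm),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out[order(out$trio_id, out$class), , drop = FALSE]
  })
}
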