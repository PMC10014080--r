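#' Standard trio exclusions before model fitting
#'
#' Removes listed outlier trios (e.g. probands with exceedingly many DNMs
#' given the parental ages) and trios whose mother was older than
#' `max_mother_age` at conception, since the maternal age effect becomes
#' visibly nonlinear at older ages and the model is linear.
#'
#' @param trios Long-format trio table (see [simulate_trio_dataset()]).
#' @param outlier_ids Character vector of `trio_id`s to drop.
#' @param max_mother_age Oldest retained maternal age (strictly above is
#'   dropped; default 40).
#' @return Filtered trio table.
#' @export
apply_trio_filters <- function(trios, outlier_ids = character(),
                               max_mother_age = 40) {
  keep <- !(trios$trio_id %in% outlier_ids) &
    trios$mother_age <= max_mother_age
  trios[keep, , drop = FALSE]
}

# one row per trio for a single class; errors if the class is absent
class_subset <- function(trios, class) {
  d <- trios[trios$class == class, , drop = FALSE]
  if (nrow(d) == 0L) stop_mutspectra("no trios carry class ", class)
  if (anyDuplicated(d$trio_id)) {
    stop_mutspectra("multiple rows per trio for class ", class)
  }
  d
}

# means linear in age, parameterized through log means at the two ends of
# the observed age range so that means stay positive over that range
lambda_from_theta <- function(theta2, ages, amin, amax) {
  t <- (ages - amin) / (amax - amin)
  (1 - t) * exp(theta2[1L]) + t * exp(theta2[2L])
}

#' Poisson log-likelihood of a parental-age effect for one class
#'
#' Per trio, phased paternal and maternal counts are Poisson with means
#' `phi * (beta_p * Fa + alpha_p)` and `phi * (beta_m * Mo + alpha_m)`,
#' and the unphased count is Poisson with mean `(1 - phi)` times the sum,
#' where `phi` is the trio's (known) phased fraction. Because `phi`
#' enters only multiplicatively, it contributes an additive constant to
#' the log-likelihood in the parameters; this function reports the
#' parameter-dependent part (no factorial or `log(phi)` constants), so
#' differences between parameter values are exact.
#'
#' @param effect A [parental_age_effect()].
#' @param trios Long-format trio table.
#' @param class Class label to evaluate.
#' @return Scalar log-likelihood (up to an additive constant).
#' @export
dnm_loglik <- function(effect, trios, class = effect$class) {
  d <- class_subset(trios, class)
  lam_p <- effect$beta_p * d$father_age + effect$alpha_p
  lam_m <- effect$beta_m * d$mother_age + effect$alpha_m
  if (any(lam_p < 0) || any(lam_m < 0)) return(-Inf)
  yl <- function(y, lam) ifelse(y == 0, 0, y * log(lam))
  sum(yl(d$phased_paternal, lam_p) + yl(d$phased_maternal, lam_m) +
        yl(d$unphased, lam_p + lam_m) - (lam_p + lam_m))
}

#' Fit sex-specific linear parental-age effects by Poisson ML
#'
#' Maximizes the likelihood in [dnm_loglik()] for one mutation class,
#' using all phased and unphased DNMs. Non-negativity of the predicted
#' means over the observed age range is enforced by parameterizing each
#' parent's mean through its log values at the youngest and oldest
#' observed age; optimization is L-BFGS-B from multiple starts (moment
#' based and flat), keeping the best optimum.
#'
#' @param trios Long-format trio table (one row per trio for `class`).
#' @param class Mutation class label to fit.
#' @return A [parental_age_effect()] with attributes `loglik`,
#'   `convergence` (0 = converged) and `n_trios`.
#' @export
fit_parental_age_model <- function(trios, class) {
  d <- class_subset(trios, class)
  fa <- d$father_age; mo <- d$mother_age
  if (length(unique(fa)) < 2L || length(unique(mo)) < 2L) {
    stop_mutspectra("unidentifiable design: need >= 2 distinct ages ",
                    "for each parent")
  }
  yp <- d$phased_paternal; ym <- d$phased_maternal; yu <- d$unphased
  if (all(yp + ym + yu == 0)) {
    eff <- parental_age_effect(class, 0, 0, 0, 0)
    attr(eff, "loglik") <- 0
    attr(eff, "convergence") <- 0L
    attr(eff, "n_trios") <- nrow(d)
    return(eff)
  }
  frng <- range(fa); mrng <- range(mo)

  tf <- (fa - frng[1L]) / (frng[2L] - frng[1L])
  tm <- (mo - mrng[1L]) / (mrng[2L] - mrng[1L])
  ip <- yp > 0; im <- ym > 0; iu <- yu > 0

  nll <- function(theta) {
    e <- exp(theta)
    lam_p <- (1 - tf) * e[1L] + tf * e[2L]
    lam_m <- (1 - tm) * e[3L] + tm * e[4L]
    lt <- lam_p + lam_m
    -(sum(yp[ip] * log(lam_p[ip])) + sum(ym[im] * log(lam_m[im])) +
        sum(yu[iu] * log(lt[iu])) - sum(lt))
  }
  ngr <- function(theta) {
    e <- exp(theta)
    lam_p <- (1 - tf) * e[1L] + tf * e[2L]
    lam_m <- (1 - tm) * e[3L] + tm * e[4L]
    lt <- lam_p + lam_m
    gp <- 1 - yp / lam_p - yu / lt   # d nll / d lam_p
    gm <- 1 - ym / lam_m - yu / lt
    c(sum(gp * (1 - tf)) * e[1L], sum(gp * tf) * e[2L],
      sum(gm * (1 - tm)) * e[3L], sum(gm * tm) * e[4L])
  }

  # moment-based start: linear fit of total counts on ages, mass split
  # between parents by the phased counts (fallback 80/20 paternal)
  tot <- yp + ym + yu
  co <- tryCatch(coef(lm(tot ~ fa + mo)), error = function(e) NULL)
  psh <- if (sum(yp + ym) > 0) sum(yp) / sum(yp + ym) else 0.8
  starts <- list()
  if (!is.null(co) && all(is.finite(co))) {
    pred_p <- function(a) psh * co[1L] + max(co[2L], 0) * a
    pred_m <- function(a) (1 - psh) * co[1L] + max(co[3L], 0) * a
    starts$moment <- log(pmax(c(pred_p(frng), pred_m(mrng)), 1e-3))
  }
  mu0 <- max(mean(tot), 1e-3)
  starts$flat <- log(c(psh * mu0, psh * mu0, (1 - psh) * mu0, (1 - psh) * mu0))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll, ngr, method = "L-BFGS-B",
            lower = rep(log(1e-8), 4L), upper = rep(log(1e5), 4L),
            control = list(factr = 1e-8 / .Machine$double.eps,
                           maxit = 500L)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_mutspectra("parental-age model failed to converge")

  th <- best$par
  to_ab <- function(t2, rng) {
    beta <- (exp(t2[2L]) - exp(t2[1L])) / (rng[2L] - rng[1L])
    alpha <- exp(t2[1L]) - beta * rng[1L]
    c(alpha = alpha, beta = beta)
  }
  ab_p <- to_ab(th[1:2], frng); ab_m <- to_ab(th[3:4], mrng)
  eff <- parental_age_effect(class,
                             alpha_p = ab_p[1L], beta_p = ab_p[2L],
                             alpha_m = ab_m[1L], beta_m = ab_m[2L],
                             age_range = list(paternal = frng,
                                              maternal = mrng))
  attr(eff, "loglik") <- -best$value
  attr(eff, "convergence") <- best$convergence
  attr(eff, "n_trios") <- nrow(d)
  eff
}

#' Bootstrap the parental-age effect by resampling trios
#'
#' Resamples trios with replacement and refits the model; uncertainty is
#' summarized by percentile intervals over the replicates (see
#' [effect_ci()]).
#'
#' @param trios Long-format trio table.
#' @param class Class label.
#' @param n_reps Number of bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @return Object of class `"bootstrap_set"`: list with `replicates`
#'   (list of effects, `NULL` where a refit failed, so replicate sets of
#'   two classes drawn with the same seed stay paired by resample
#'   index), `n_failed`, `class`, `seed`, and `indices` (the resample
#'   index matrix).
#' @export
bootstrap_effects <- function(trios, class, n_reps = 500L, seed = 1L) {
  if (n_reps < 1L) stop_mutspectra("n_reps must be >= 1")
  d <- class_subset(trios, class)
  n <- nrow(d)
  idx <- with_seed(seed, matrix(sample.int(n, n * n_reps, replace = TRUE),
                                nrow = n, ncol = n_reps))
  reps <- vector("list", n_reps)
  failed <- 0L
  for (r in seq_len(n_reps)) {
    db <- d[idx[, r], , drop = FALSE]
    db$trio_id <- sprintf("bs%06d", seq_len(n))
    reps[[r]] <- tryCatch(fit_parental_age_model(db, class),
                          error = function(e) NULL)
    if (is.null(reps[[r]])) failed <- failed + 1L
  }
  structure(
    list(replicates = reps, n_failed = failed,
         class = class, seed = seed, indices = idx),
    class = "bootstrap_set"
  )
}

#' Percentile confidence intervals of bootstrapped effect parameters
#'
#' @param boot A [bootstrap_effects()] result.
#' @param level Coverage level (default 0.90).
#' @return Matrix with rows alpha_p, beta_p, alpha_m, beta_m and columns
#'   `lower`, `upper`.
#' @export
effect_ci <- function(boot, level = 0.90) {
  stopifnot(inherits(boot, "bootstrap_set"))
  pars <- c("alpha_p", "beta_p", "alpha_m", "beta_m")
  a <- (1 - level) / 2
  reps <- Filter(Negate(is.null), boot$replicates)
  if (length(reps) == 0L) stop_mutspectra("no successful bootstrap replicates")
  out <- t(vapply(pars, function(p) {
    v <- vapply(reps, `[[`, numeric(1L), p)
    quantile(v, c(a, 1 - a), names = FALSE)
  }, numeric(2L)))
  colnames(out) <- c("lower", "upper")
  out
}

#' Contrast of the CpG C>T / CpG C>A ratio between parental-age quintiles
#'
#' Ranks trios by a parental-age score (sum of both parents' ages by
#' default), takes the 20% of trios with the youngest and oldest parents,
#' and compares the ratio of total CpG C>T to CpG C>A DNM counts between
#' the two groups with a 2 x 2 chi-square test. A declining ratio with
#' age indicates that the CpG C>T fraction decreases as parents age.
#'
#' @param trios Long-format trio table containing classes `"C>T_CpG"`
#'   and `"C>A_CpG"`.
#' @param age_score `"combined"` (Fa + Mo), `"paternal"`, or
#'   `"maternal"`.
#' @return List with `ratio_young`, `ratio_old`, `p_value`, and `counts`
#'   (the 2 x 2 table).
#' @export
quintile_cpg_ratio_test <- function(trios,
                                    age_score = c("combined", "paternal",
                                                  "maternal")) {
  age_score <- match.arg(age_score)
  ct <- class_subset(trios, "C>T_CpG")
  ca <- class_subset(trios, "C>A_CpG")
  ca <- ca[match(ct$trio_id, ca$trio_id), , drop = FALSE]
  if (anyNA(ca$trio_id)) stop_mutspectra("trio sets differ between classes")
  score <- switch(age_score,
                  combined = ct$father_age + ct$mother_age,
                  paternal = ct$father_age,
                  maternal = ct$mother_age)
  n <- nrow(ct)
  ord <- order(score)
  k <- max(1L, floor(0.2 * n))
  young <- ord[seq_len(k)]
  old <- ord[seq.int(n - k + 1L, n)]
  tot <- function(d, i) sum(d$phased_paternal[i] + d$phased_maternal[i] +
                              d$unphased[i])
  tab <- rbind(ct = c(young = tot(ct, young), old = tot(ct, old)),
               ca = c(young = tot(ca, young), old = tot(ca, old)))
  if (any(tab["ca", ] == 0)) {
    stop_mutspectra("zero CpG C>A count in a quintile; ratio undefined")
  }
  chi <- interpopulation_chisq(tab)
  list(ratio_young = tab["ct", "young"] / tab["ca", "young"],
       ratio_old = tab["ct", "old"] / tab["ca", "old"],
       p_value = chi$p_value, counts = tab)
}
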