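#' Define a time-varying mutation-spectrum scenario
#'
#' A scenario is a set of disjoint, ordered age epochs (in generations),
#' each with its own probability vector over mutation classes; variants
#' are drawn within epochs with true ages uniform over the epoch and
#' lognormal relative age-uncertainty half-widths, emulating the
#' order-of-magnitude uncertainty of genealogy-based allele ages.
#'
#' @param epochs List of lists with `age_start`, `age_end` (generations)
#'   and `class_fractions` (named probability vector over mutation
#'   classes summing to 1).
#' @param n_variants Total number of variants to draw.
#' @param populations Named list mapping population label to presence
#'   probability (scalar, or vector with one entry per epoch).
#' @param age_interval List with `meanlog` and `sdlog` of the lognormal
#'   relative half-width of the age-uncertainty interval (default median
#'   0.5 x the true age).
#' @param epoch_weights Sampling weights of the epochs; default
#'   proportional to epoch duration.
#' @param seed Integer seed.
#' @return Object of class `"spectrum_scenario"`.
#' @export
spectrum_scenario <- function(epochs, n_variants,
                              populations = list(CEU = 1.0),
                              age_interval = list(meanlog = log(0.5),
                                                  sdlog = 0.5),
                              epoch_weights = NULL, seed = 1L) {
  if (length(epochs) == 0L) stop_mutspectra("at least one epoch is required")
  starts <- vapply(epochs, `[[`, numeric(1L), "age_start")
  ends <- vapply(epochs, `[[`, numeric(1L), "age_end")
  if (any(ends <= starts)) stop_mutspectra("epochs must have age_end > age_start")
  if (is.unsorted(starts, strictly = TRUE) ||
      any(starts[-1L] < ends[-length(ends)])) {
    stop_mutspectra("epochs must be disjoint and ordered by age")
  }
  for (e in epochs) {
    f <- e$class_fractions
    if (is.null(names(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-9) {
      stop_mutspectra("class_fractions must be a named non-negative vector ",
                      "summing to 1 (within 1e-9)")
    }
  }
  if (n_variants < 1L) stop_mutspectra("n_variants must be positive")
  if (is.null(epoch_weights)) epoch_weights <- ends - starts
  structure(
    list(epochs = epochs, n_variants = as.integer(n_variants),
         populations = populations, age_interval = age_interval,
         epoch_weights = epoch_weights / sum(epoch_weights), seed = seed),
    class = "spectrum_scenario"
  )
}

# uniformly draw a compatible (five_prime, three_prime) context for each
# class label (collapsed orientation), honoring CpG/TpG constraints
draw_contexts <- function(class_labels) {
  n <- length(class_labels)
  fp <- sample(DNA_BASES, n, replace = TRUE)
  tp <- sample(DNA_BASES, n, replace = TRUE)
  cpg <- grepl("_CpG$", class_labels) | grepl("_TpG$", class_labels)
  noncpg <- grepl("_non", class_labels)
  tp[cpg] <- "G"
  if (any(noncpg)) {
    tp[noncpg] <- sample(c("A", "C", "T"), sum(noncpg), replace = TRUE)
  }
  list(five_prime = fp, three_prime = tp)
}

#' Simulate a variant table under a spectrum scenario
#'
#' Each variant gets an epoch (weights `epoch_weights`), a true age
#' uniform within the epoch, a mutation class from the epoch's fractions,
#' a flanking context drawn uniformly among triplets compatible with the
#' class, and an age-uncertainty interval `[age_lower, age_upper]`
#' guaranteed to contain the true age, of full width
#' `2 * r * true_age` with `r` lognormal, positioned uniformly around the
#' true age and truncated at 0. Half of the variants are emitted on the
#' purine strand (alleles and flanks reverse complemented) to exercise
#' strand collapsing downstream. Presence in each population is an
#' independent Bernoulli draw with the scenario's per-epoch probability.
#'
#' @param scenario A [spectrum_scenario()].
#' @return Data frame with columns chrom, pos, ancestral, derived,
#'   five_prime, three_prime, age_lower, age_upper, populations, and the
#'   bookkeeping columns true_age, true_class, epoch.
#' @export
simulate_variant_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "spectrum_scenario"))
  with_seed(scenario$seed, {
    n <- scenario$n_variants
    ne <- length(scenario$epochs)
    epoch <- sample.int(ne, n, replace = TRUE, prob = scenario$epoch_weights)
    starts <- vapply(scenario$epochs, `[[`, numeric(1L), "age_start")
    ends <- vapply(scenario$epochs, `[[`, numeric(1L), "age_end")
    age <- runif(n, starts[epoch], ends[epoch])

    cls <- character(n)
    for (e in seq_len(ne)) {
      idx <- which(epoch == e)
      f <- scenario$epochs[[e]]$class_fractions
      if (length(idx)) {
        cls[idx] <- sample(names(f), length(idx), replace = TRUE, prob = f)
      }
    }

    ctx <- draw_contexts(cls)
    base_class <- sub("_.*$", "", cls)
    anc <- substr(base_class, 1L, 1L)
    der <- substr(base_class, 3L, 3L)

    rel <- exp(rnorm(n, scenario$age_interval$meanlog,
                     scenario$age_interval$sdlog))
    width <- 2 * rel * age
    lower <- pmax(0, age - runif(n) * width)
    upper <- lower + width
    upper <- pmax(upper, age)  # guard after truncation at 0

    flip <- runif(n) < 0.5
    fp <- ctx$five_prime; tp <- ctx$three_prime
    anc_out <- ifelse(flip, complement_base(anc), anc)
    der_out <- ifelse(flip, complement_base(der), der)
    fp_out <- ifelse(flip, complement_base(tp), fp)
    tp_out <- ifelse(flip, complement_base(fp), tp)

    pres <- matrix(FALSE, n, length(scenario$populations))
    pops <- names(scenario$populations)
    for (j in seq_along(pops)) {
      pr <- rep_len(scenario$populations[[j]], ne)
      pres[, j] <- runif(n) < pr[epoch]
    }
    populations <- apply(pres, 1L, function(r) paste(pops[r], collapse = ","))

    data.frame(
      chrom = "1",
      pos = sample.int(2.5e8, n, replace = TRUE),
      ancestral = anc_out, derived = der_out,
      five_prime = fp_out, three_prime = tp_out,
      age_lower = lower, age_upper = upper,
      populations = populations,
      true_age = age, true_class = cls, epoch = epoch,
      stringsAsFactors = FALSE
    )
  })
}
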