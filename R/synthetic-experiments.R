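#' Specification of an immunomagnetic leukocyte-depletion run
#'
#' Parameters of the negative-selection split of a Feed sample into the
#' non-magnetic Eluate (CMC-enriched) and the magnetically retained
#' Retentate (leukocyte-rich). The separator described by this model removes
#' 98-99% of CD45-labelled leukocytes while spiked tumour cells are
#' essentially fully recovered in the Eluate.
#'
#' @param feed_leukocytes,feed_cmcs cell counts loaded into the separator.
#' @param depletion_efficiency probability in `[0,1]` that a leukocyte is
#'   retained on the magnet (default 0.985, the middle of the 98-99% range).
#' @param cmc_loss probability in `[0,1]` that a CMC is lost to the
#'   Retentate (default 0.02; spiked cells are near-fully recovered).
#' @param seed integer seed.
#' @return An object of class `separation_spec`.
#' @export
separation_spec <- function(feed_leukocytes, feed_cmcs,
                            depletion_efficiency = 0.985, cmc_loss = 0.02,
                            seed = 1L) {
  if (!is_count(feed_leukocytes) || !is_count(feed_cmcs))
    stopf("feed counts must be non-negative integers")
  for (p in c(depletion_efficiency, cmc_loss))
    if (!is.numeric(p) || p < 0 || p > 1)
      stopf("depletion_efficiency and cmc_loss must lie in [0,1]")
  structure(list(feed_leukocytes = feed_leukocytes, feed_cmcs = feed_cmcs,
                 depletion_efficiency = depletion_efficiency,
                 cmc_loss = cmc_loss, seed = as.integer(seed)),
            class = "separation_spec")
}

#' Simulate one pass through the magnetic separator
#'
#' Each leukocyte is independently retained with probability
#' `depletion_efficiency` and each CMC lost with probability `cmc_loss`
#' (binomial draws); Eluate and Retentate together always equal the Feed
#' exactly, population by population.
#'
#' @param spec a [separation_spec()].
#' @return List of class `separation_result` with `eluate` and `retentate`,
#'   each `list(leukocytes =, cmcs =)`, plus the `feed` composition.
#' @export
simulate_separation <- function(spec) {
  stopifnot(inherits(spec, "separation_spec"))
  with_seed(spec$seed, {
    retained_leuko <- as.numeric(
      rbinom(1, spec$feed_leukocytes, spec$depletion_efficiency))
    lost_cmc <- as.numeric(rbinom(1, spec$feed_cmcs, spec$cmc_loss))
    feed_l <- as.numeric(spec$feed_leukocytes)
    feed_c <- as.numeric(spec$feed_cmcs)
    structure(list(
      feed = list(leukocytes = feed_l, cmcs = feed_c),
      eluate = list(leukocytes = feed_l - retained_leuko,
                    cmcs = feed_c - lost_cmc),
      retentate = list(leukocytes = retained_leuko, cmcs = lost_cmc)),
      class = "separation_result")
  })
}

#' Simulate a spike-in recovery series
#'
#' Emulates experiments in which known numbers of cultured melanoma cells
#' per mL are spiked into healthy-donor blood, separated and counted in the
#' Eluate: each spiked cell is recovered with probability `recovery_rate`
#' (binomial) on top of a Poisson healthy background.
#'
#' @param levels spiked concentrations (cells per mL), non-negative.
#' @param recovery_rate per-cell recovery probability in `[0,1]`.
#' @param background_per_ml expected marker-positive background per mL in
#'   unspiked blood (healthy donors show 0-3 per mL).
#' @param replicates replicates per level.
#' @param seed integer seed.
#' @return data.frame with columns `spiked`, `recovered`, `replicate`.
#' @export
simulate_spike_series <- function(levels, recovery_rate = 0.95,
                                  background_per_ml = 1, replicates = 3,
                                  seed = 1L) {
  if (any(levels < 0) || any(levels != floor(levels)))
    stopf("spike levels must be non-negative integer counts per mL")
  if (recovery_rate < 0 || recovery_rate > 1)
    stopf("recovery_rate must lie in [0,1]")
  if (background_per_ml < 0) stopf("background_per_ml must be >= 0")
  if (!is_count(replicates) || replicates < 1)
    stopf("replicates must be a count >= 1")
  with_seed(seed, {
    spiked <- rep(as.integer(levels), each = replicates)
    data.frame(
      spiked = spiked,
      recovered = rbinom(length(spiked), spiked, recovery_rate) +
        rpois(length(spiked), background_per_ml),
      replicate = rep(seq_len(replicates), times = length(levels)))
  })
}

#' Specification of a synthetic survival cohort
#'
#' Defines a cohort with a known relationship between per-mL CMC count and
#' overall survival, used to verify that the Cox fit recovers a planted
#' log-hazard ratio. Counts are lognormal; survival is exponential with
#' hazard `baseline_hazard * exp(true_log_hazard_ratio * ln(count))` and
#' administrative censoring at `censor_time`.
#'
#' Defaults emulate the published cohort regime: median count 287/mL
#' (`log_count_mean = log(287)`), counts spanning tens to tens of thousands
#' (`log_count_sd = 1.8`), a hazard ratio of 1.46 per e-fold of count
#' (`true_log_hazard_ratio = log(1.46)`) and about three years of follow-up.
#'
#' @param n_patients cohort size (>= 2).
#' @param log_count_mean,log_count_sd natural-log mean and sd of counts.
#' @param true_log_hazard_ratio planted log hazard ratio per ln(count) unit.
#' @param baseline_hazard events per month at ln(count) = 0.
#' @param censor_time administrative censoring time in months.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, log_count_mean = log(287),
                        log_count_sd = 1.8,
                        true_log_hazard_ratio = log(1.46),
                        baseline_hazard = 0.007, censor_time = 36,
                        seed = 1L) {
  if (!is_count(n_patients) || n_patients < 2)
    stopf("n_patients must be a count >= 2")
  if (log_count_sd <= 0) stopf("log_count_sd must be > 0")
  if (baseline_hazard <= 0) stopf("baseline_hazard must be > 0")
  if (censor_time < 0) stopf("censor_time must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 log_count_mean = log_count_mean,
                 log_count_sd = log_count_sd,
                 true_log_hazard_ratio = true_log_hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censor_time = censor_time, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with `patient_id`, `survival_months`, `event`
#'   (TRUE = death observed; FALSE = censored, i.e. alive at analysis) and
#'   `n_cmc_ml`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    counts <- rlnorm(spec$n_patients, spec$log_count_mean, spec$log_count_sd)
    hazard <- spec$baseline_hazard *
      exp(spec$true_log_hazard_ratio * log(counts))
    t_death <- rexp(spec$n_patients, hazard)
    event <- t_death <= spec$censor_time
    data.frame(patient_id = seq_len(spec$n_patients),
               survival_months = pmin(t_death, spec$censor_time),
               event = event,
               n_cmc_ml = counts)
  })
}
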