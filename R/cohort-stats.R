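#' The published melanoma patient table
#'
#' Returns the packaged patient table of the 11 Stage IV metastatic
#' melanoma samples: survival months, censoring flag (alive at analysis),
#' per-slide CMC count with its Poisson CV%, per-mL CMC concentration,
#' BRAF V600E status, metastasis site, marker used and sex.
#'
#' @return data.frame with one row per patient.
#' @export
melanoma_cohort <- function() {
  path <- system.file("extdata", "melanoma_cohort.csv", package = "cmcount",
                      mustWork = TRUE)
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$alive_at_analysis <- as.logical(out$alive_at_analysis)
  out
}

#' Synthetic healthy-control per-mL counts
#'
#' Healthy donors processed with the same protocol show 0-3
#' marker-positive cells per mL; the exact per-donor values are not
#' published, so this packaged stand-in holds 10 synthetic values in that
#' range (mostly 0-1, reflecting "no, or occasional low" positives).
#'
#' @return data.frame with `donor_id` and `n_cmc_ml`.
#' @export
healthy_controls <- function() {
  path <- system.file("extdata", "healthy_controls_synthetic.csv",
                      package = "cmcount", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Summaries of a patient cohort
#'
#' @param records data.frame with at least `n_cmc_ml`; optional factor-like
#'   columns `sex`, `site`, `braf_status`, `marker` are tabulated when
#'   present.
#' @return List with `n`, `median`, `min`, `max` of the per-mL counts and
#'   any available demographic tabulations.
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stopf("empty cohort table")
  if (!"n_cmc_ml" %in% names(records))
    stopf("cohort table must have an n_cmc_ml column")
  out <- list(n = nrow(records),
              median = median(records$n_cmc_ml),
              min = min(records$n_cmc_ml),
              max = max(records$n_cmc_ml))
  for (col in c("sex", "site", "braf_status", "marker"))
    if (col %in% names(records)) out[[paste0("by_", col)]] <- table(records[[col]])
  out
}

#' Exact Mann-Whitney U test (ties allowed)
#'
#' Two-sided Mann-Whitney test with the exact conditional null
#' distribution of the rank sum given the observed (possibly tied) pooled
#' values, computed by dynamic-programming convolution over all
#' `choose(n_a + n_b, n_a)` group labelings. For combined samples larger
#' than `exact_max` a normal approximation with tie correction is used.
#' The two-sided p is `2 * min(lower tail, upper tail)` capped at 1.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @param exact_max largest combined sample size for exact mode
#'   (default 25).
#' @return List with `U` (statistic of `group_a`), `p`, `method`.
#' @export
mann_whitney_exact <- function(group_a, group_b, exact_max = 25) {
  m <- length(group_a); n <- length(group_b)
  if (m == 0 || n == 0) stopf("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)           # average ranks for ties
  s <- as.integer(round(2 * r))  # doubled ranks are integers
  r_obs <- sum(s[seq_len(m)])
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  N <- m + n

  if (N <= exact_max) {
    S <- sum(s)
    # ways[k+1, t+1] = number of size-k subsets with doubled-rank-sum t
    ways <- matrix(0, m + 1, S + 1)
    ways[1, 1] <- 1
    for (j in seq_len(N)) {
      kmax <- min(j, m)
      for (k in kmax:1) {
        src <- ways[k, seq_len(S + 1 - s[j])]
        idx <- (s[j] + 1):(S + 1)
        ways[k + 1, idx] <- ways[k + 1, idx] + src
      }
    }
    dist <- ways[m + 1, ]
    total <- sum(dist)            # = choose(N, m)
    lo <- sum(dist[seq_len(r_obs + 1)]) / total
    hi <- sum(dist[(r_obs + 1):(S + 1)]) / total
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- m * n / 2
    ties_tab <- table(pooled)
    tie_adj <- sum(ties_tab^3 - ties_tab) / (N * (N - 1))
    v <- m * n / 12 * ((N + 1) - tie_adj)
    if (v <= 0) { p <- 1 } else {
      z <- (U - mu) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p = p, method = method)
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits overall survival on a single covariate (here typically the
#' log-transformed per-mL CMC count) by partial likelihood, Breslow tie
#' handling by default, and reports the hazard ratio with a 95% Wald
#' interval `exp(beta +/- 1.96 se)`.
#'
#' @param times survival times (months).
#' @param events logical/0-1 event indicators (TRUE = death observed;
#'   patients alive at analysis are censored).
#' @param covariate numeric covariate.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List of class `cox_fit`: `beta`, `se`, `hr`, `hr_ci`, `p`
#'   (Wald), `n`, `n_events`, `ties`.
#' @export
cox_ph_single <- function(times, events, covariate,
                          ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  events <- as.logical(events)
  if (length(times) != length(events) || length(times) != length(covariate))
    stopf("times, events and covariate must have equal length")
  if (sum(events) == 0)
    stopf("no events observed: the partial likelihood is uninformative")
  if (length(unique(covariate)) < 2)
    stopf("constant covariate: no information to estimate a hazard ratio")
  fit <- survival::coxph(survival::Surv(times, events) ~ covariate,
                         ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  if (fit$iter >= 100)
    stopf("Cox fit did not converge in 100 iterations (last beta = %.4f)",
          coef(fit)[1])
  beta <- unname(coef(fit)[1])
  se <- sqrt(unname(fit$var[1, 1]))
  structure(list(beta = beta, se = se, hr = exp(beta),
                 hr_ci = exp(beta + c(-1.96, 1.96) * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 n = length(times), n_events = sum(events), ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(paste0("<cox_fit> HR %.3f, 95%% CI (%.3f, %.3f), p = %.3f ",
                     "(beta %.3f, se %.3f; %d events / %d subjects, %s ties)\n"),
              x$hr, x$hr_ci[1], x$hr_ci[2], x$p, x$beta, x$se,
              x$n_events, x$n, x$ties))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param times survival times.
#' @param events logical/0-1 event indicators.
#' @param group binary group labels (both groups non-empty).
#' @return List with `chisq` (1 df) and `p`.
#' @export
logrank_test <- function(times, events, group) {
  events <- as.logical(events)
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2)
    stopf("group must have exactly two non-empty levels")
  if (sum(events) == 0) stopf("no events observed: log-rank is undefined")
  sd1 <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chisq = unname(sd1$chisq),
       p = stats::pchisq(sd1$chisq, df = 1, lower.tail = FALSE))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; two-sided p from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df
#' (p = 0 at |rho| = 1).
#'
#' @param x,y numeric vectors, length >= 3.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stopf("x and y must have equal length")
  if (n < 3) stopf("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stopf("constant vector: rank correlation is undefined")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' qPCR fold enrichment (Eluate vs Feed) by the delta-delta-Ct method
#'
#' Target miR Ct values are normalised to the U6 reference within each
#' fraction and compared between fractions:
#' `fold = 2^-((ct_target_eluate - ct_ref_eluate) -
#' (ct_target_feed - ct_ref_feed))`.
#'
#' @param ct_target_feed,ct_ref_feed,ct_target_eluate,ct_ref_eluate qPCR
#'   cycle-threshold values (all > 0; vectors recycle as usual).
#' @return Fold enrichment of the target in the Eluate relative to the
#'   Feed.
#' @export
mir_fold_change <- function(ct_target_feed, ct_ref_feed,
                            ct_target_eluate, ct_ref_eluate) {
  cts <- list(ct_target_feed, ct_ref_feed, ct_target_eluate, ct_ref_eluate)
  if (any(vapply(cts, function(v) any(is.na(v)) || !length(v), logical(1))))
    stopf("all four Ct values must be present")
  if (any(unlist(cts) <= 0)) stopf("Ct values must be > 0")
  ddct <- (ct_target_eluate - ct_ref_eluate) -
    (ct_target_feed - ct_ref_feed)
  2^(-ddct)
}
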