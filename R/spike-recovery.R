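#' Spike-in recovery regression
#'
#' Ordinary least squares of recovered on spiked concentration with
#' two-sided 95% t-intervals, as used to show that spiked melanoma cells
#' are fully recovered in the Eluate fraction (slope near 1 with the
#' identity line inside the confidence band).
#'
#' @param experiments data.frame with columns `spiked` and `recovered`
#'   (e.g. from [simulate_spike_series()]); at least 3 points spanning at
#'   least 2 distinct spike levels.
#' @return List of class `recovery_fit`: `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci` (95% intervals), `r_squared`, `n`. With an exact linear
#'   relationship the residual variance is zero and the intervals collapse
#'   to the point estimates.
#' @export
recovery_regression <- function(experiments) {
  if (!all(c("spiked", "recovered") %in% names(experiments)))
    stopf("experiments must have columns 'spiked' and 'recovered'")
  x <- experiments$spiked; y <- experiments$recovered
  if (length(x) < 3) stopf("need at least 3 spike observations")
  if (length(unique(x)) < 2)
    stopf("all spiked levels are equal: regression is rank-deficient")
  fit <- lm(y ~ x)
  # suppress the "essentially perfect fit" notice: noiseless series are a
  # documented degenerate case with point-mass intervals
  ci <- suppressWarnings(confint(fit, level = 0.95))
  ci[is.na(ci)] <- rep(coef(fit), 2)[is.na(ci)]
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    slope_ci = unname(ci[2, ]), intercept_ci = unname(ci[1, ]),
    r_squared = suppressWarnings(summary(fit))$r.squared, n = length(x)),
    class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(paste0("<recovery_fit> slope %.3f [%.3f, %.3f], intercept ",
                     "%.2f [%.2f, %.2f], R^2 %.4f (n = %d)\n"),
              x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept,
              x$intercept_ci[1], x$intercept_ci[2], x$r_squared, x$n))
  invisible(x)
}

#' Limit of detection from a spike series
#'
#' Operational definition: the smallest spike level whose recovered counts
#' exceed the maximum healthy-donor background in at least `prob` of
#' replicates (strict exceedance, so ties with the background resolve
#' conservatively upward).
#'
#' @param experiments data.frame with `spiked` and `recovered`.
#' @param background healthy-donor per-mL counts (non-empty).
#' @param prob required exceedance probability (default 0.95).
#' @return The LOD in cells per mL, or `Inf` when no tested level
#'   qualifies (i.e. the LOD lies above the maximum tested level).
#' @export
limit_of_detection <- function(experiments, background, prob = 0.95) {
  if (!all(c("spiked", "recovered") %in% names(experiments)))
    stopf("experiments must have columns 'spiked' and 'recovered'")
  if (!length(background)) stopf("background must be non-empty")
  if (prob <= 0 || prob > 1) stopf("prob must be in (0, 1]")
  b <- max(background)
  levels <- sort(unique(experiments$spiked))
  for (lv in levels) {
    rec <- experiments$recovered[experiments$spiked == lv]
    if (mean(rec > b) >= prob) return(lv)
  }
  Inf
}
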