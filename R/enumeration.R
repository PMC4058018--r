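#' Poisson counting coefficient of variation
#'
#' The relative standard deviation attributed to counting `n` rare events
#' on one slide, `100 / sqrt(n)` percent, reported to 2 significant
#' figures.
#'
#' @param n slide count (integer >= 1).
#' @param digits significant figures for reporting (default 2); `NULL`
#'   returns the unrounded value.
#' @return CV in percent.
#' @export
#' @examples
#' poisson_cv(101)  # 10
#' poisson_cv(2134) # 2.2
poisson_cv <- function(n, digits = 2) {
  if (any(!vapply(n, is_count, logical(1))) || any(n < 1))
    stopf("Poisson CV is undefined for counts below 1")
  cv <- 100 / sqrt(n)
  if (is.null(digits)) cv else signif(cv, digits)
}

#' Extrapolate a slide CMC count to cells per mL of blood
#'
#' A cytospin slide carries `cells_per_slide` cells out of
#' `total_cells_in_fraction` in the counted fraction, so the slide samples
#' a fraction `cells_per_slide / total_cells_in_fraction` of the blood
#' draw; the per-mL concentration is the slide count scaled by the inverse
#' of that sampling ratio and divided by the blood volume:
#' `n_cmc_slide * (total_cells_in_fraction / cells_per_slide) /
#' blood_volume_ml`.
#'
#' @param n_cmc_slide CMCs counted on the slide.
#' @param total_cells_in_fraction total viable cells in the fraction the
#'   slide was prepared from (viability-counter estimate).
#' @param cells_per_slide cells deposited per cytospin slide (default
#'   50,000).
#' @param blood_volume_ml blood volume analysed, in mL (default 10).
#' @param round round the reported concentration to an integer (default
#'   TRUE, matching how per-mL counts are tabulated).
#' @return CMCs per mL of blood.
#' @export
#' @examples
#' per_ml(10, 5e5, 5e4, 1)      # 100
#' per_ml(4, 2.625e6, 5e4, 10)  # 21
per_ml <- function(n_cmc_slide, total_cells_in_fraction,
                   cells_per_slide = 5e4, blood_volume_ml = 10,
                   round = TRUE) {
  if (any(n_cmc_slide < 0)) stopf("n_cmc_slide must be >= 0")
  if (any(total_cells_in_fraction <= 0) || any(cells_per_slide <= 0))
    stopf("cell counts must be positive")
  if (any(blood_volume_ml <= 0)) stopf("blood_volume_ml must be positive")
  if (any(cells_per_slide > total_cells_in_fraction))
    warnf(paste0("cells_per_slide exceeds total_cells_in_fraction: the ",
                 "slide oversamples the fraction"))
  x <- n_cmc_slide * (total_cells_in_fraction / cells_per_slide) /
    blood_volume_ml
  if (round) base::round(x) else x
}

#' Cell-number mass balance of a separation run
#'
#' Self-consistency check of the separator: the cells found in Eluate plus
#' Retentate should account for the Feed.
#'
#' @param feed,eluate,retentate total cell counts per fraction.
#' @param tol tolerated relative imbalance (default 0.15).
#' @return List with `recovery` (`(eluate + retentate) / feed`) and `pass`.
#' @export
mass_balance <- function(feed, eluate, retentate, tol = 0.15) {
  if (feed <= 0) stopf("feed count must be > 0")
  if (eluate < 0 || retentate < 0) stopf("fraction counts must be >= 0")
  recovery <- (eluate + retentate) / feed
  list(recovery = recovery, pass = abs(1 - recovery) <= tol)
}

#' Leukocyte depletion rate of a separation run
#'
#' @param feed_leuko leukocytes in the Feed (> 0).
#' @param eluate_leuko leukocytes remaining in the Eluate.
#' @return Fraction depleted, `1 - eluate_leuko / feed_leuko` (0.98-0.99
#'   for the separator modelled here).
#' @export
depletion_rate <- function(feed_leuko, eluate_leuko) {
  if (feed_leuko <= 0) stopf("feed_leuko must be > 0")
  if (eluate_leuko < 0) stopf("eluate_leuko must be >= 0")
  if (eluate_leuko > feed_leuko)
    stopf("eluate_leuko exceeds feed_leuko: impossible depletion")
  1 - eluate_leuko / feed_leuko
}

#' Read a sample manifest
#'
#' @param path CSV with columns `sample_id`, `fraction` (Feed, Eluate or
#'   Retentate), `total_cells`, `cells_per_slide`, `blood_volume_ml` and
#'   optionally `slide_dir`.
#' @return Validated data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "fraction", "total_cells", "cells_per_slide",
            "blood_volume_ml")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stopf("manifest %s is missing columns: %s", path,
          paste(missing, collapse = ", "))
  bad <- which(!man$fraction %in% c("Feed", "Eluate", "Retentate") |
                 man$total_cells <= 0 | man$cells_per_slide <= 0 |
                 man$blood_volume_ml <= 0)
  if (length(bad))
    stopf("manifest %s has invalid rows: %s", path,
          paste(bad, collapse = ", "))
  man
}
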