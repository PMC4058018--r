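#' Isodata (intermeans) automatic threshold
#'
#' The iterative intermeans algorithm used as the default automatic
#' threshold in ImageJ, on the 0-255 scale: starting from the midpoint of
#' the occupied intensity range, the threshold is repeatedly replaced by the
#' rounded mean of the below-threshold and above-threshold class means until
#' it no longer changes. A pixel is considered foreground when its intensity
#' exceeds the returned threshold.
#'
#' @param x either an integer image matrix with values in 0-255, or a
#'   numeric vector of 256 histogram counts for intensities 0..255.
#' @return The fixed-point threshold `t` (integer in 0..254) satisfying
#'   `t == round((mean_below(t) + mean_above(t)) / 2)` with classes
#'   `<= t` and `> t`.
#' @export
isodata_threshold <- function(x) {
  h <- if (is.matrix(x)) {
    if (min(x) < 0 || max(x) > 255) stopf("image intensities must be in 0-255")
    tabulate(as.integer(x) + 1L, 256L)
  } else {
    if (length(x) != 256L) stopf("histogram must have 256 bins (0..255)")
    if (any(x < 0)) stopf("histogram counts must be non-negative")
    as.numeric(x)
  }
  occ <- which(h > 0) - 1L
  if (length(occ) < 2L)
    stopf("degenerate histogram: fewer than two occupied intensity levels")
  v <- 0:255
  t_cur <- floor((min(occ) + max(occ)) / 2)
  for (iter in 1:256) {
    lo <- v <= t_cur
    m_below <- sum(v[lo] * h[lo]) / sum(h[lo])
    m_above <- sum(v[!lo] * h[!lo]) / sum(h[!lo])
    t_new <- round((m_below + m_above) / 2)
    if (t_new == t_cur) return(as.integer(t_cur))
    t_cur <- t_new
  }
  as.integer(t_cur)  # cycle-free in practice; last iterate as fallback
}

#' Select global red/green classification thresholds
#'
#' Reproduces the user step of choosing global channel thresholds from the
#' per-cell fluorescence intensity scatterplot: by default the isodata
#' threshold of the per-cell green-mean and red-mean distributions. Because
#' some patient slides carry high green background from the dual-antibody
#' sandwich assay, `mode = "patient"` biases against green by multiplying
#' the green threshold by `stringency` (> 1); `mode = "control"` biases
#' toward green by dividing by it; `mode = "explicit"` passes user-chosen
#' thresholds through unchanged.
#'
#' @param cells measured-cell table from [measure_cells()] (needs
#'   `green_mean` and `red_mean` columns); at least 10 cells unless
#'   `mode = "explicit"`.
#' @param mode `"patient"`, `"control"` or `"explicit"`.
#' @param stringency multiplicative green-bias factor (> 1), default 1.25.
#' @param t_red,t_green explicit thresholds (required for
#'   `mode = "explicit"`).
#' @return List of class `threshold_pair` with `t_red`, `t_green`, `mode`.
#' @export
select_thresholds <- function(cells, mode = c("patient", "control", "explicit"),
                              stringency = 1.25,
                              t_red = NULL, t_green = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit") {
    if (is.null(t_red) || is.null(t_green))
      stopf("mode = 'explicit' requires both t_red and t_green")
    if (t_red < 0 || t_red > 255 || t_green < 0 || t_green > 255)
      stopf("explicit thresholds must be in [0, 255]")
    return(structure(list(t_red = t_red, t_green = t_green, mode = mode),
                     class = "threshold_pair"))
  }
  if (stringency <= 1) stopf("stringency must be > 1")
  if (is.null(cells) || nrow(cells) < 10)
    stopf(paste0("too few measured cells (%d) to derive thresholds from the ",
                 "intensity distribution; supply mode = 'explicit' with ",
                 "t_red and t_green"), if (is.null(cells)) 0 else nrow(cells))
  # a channel whose per-cell means all coincide offers no separation: use
  # that single level as the threshold (no cell exceeds it before biasing)
  channel_threshold <- function(v) {
    h <- tabulate(pmin(255L, pmax(0L, as.integer(round(v)))) + 1L, 256L)
    if (sum(h > 0) < 2L) which(h > 0) - 1L else isodata_threshold(h)
  }
  tg <- channel_threshold(cells$green_mean)
  tr <- channel_threshold(cells$red_mean)
  tg <- if (mode == "patient") min(255, tg * stringency) else tg / stringency
  structure(list(t_red = tr, t_green = tg, mode = mode),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair> t_red = %.1f, t_green = %.1f (mode %s)\n",
              x$t_red, x$t_green, x$mode))
  invisible(x)
}
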