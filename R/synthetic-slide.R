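#' Render a whole synthetic cytospin slide as a set of fields of view
#'
#' Distributes slide-total object counts over `n_fov` fields of view
#' (multinomial thinning with equal field probabilities, so per-FOV counts of
#' a rare class are Poisson-like while the slide totals are conserved
#' exactly) and renders each FOV with [make_fov()]. FOVs are arranged on a
#' near-square reference grid.
#'
#' @param spec a [scene_spec()] whose counts are interpreted as slide totals.
#' @param n_fov number of fields of view (>= 1).
#' @param render if `FALSE`, skip image rendering and return the ground
#'   truth allocation only (fast path for statistical checks of the
#'   thinning).
#' @return A list of class `slide_image_set`: `images` (list of `fov_image`,
#'   empty when `render = FALSE`), `truth` (ground-truth table with an `fov`
#'   column), `n_fov`, `fov_counts` (per-FOV per-class allocation matrix) and
#'   the generating `spec`.
#' @export
make_slide <- function(spec, n_fov, render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is_count(n_fov) || n_fov < 1) stopf("n_fov must be a count >= 1")
  n_fov <- as.integer(n_fov)
  totals <- c(CMC = spec$n_cmc, leukocyte = spec$n_leuko,
              dual = spec$n_dual, debris = spec$n_debris)
  with_seed(spec$seed, {
    alloc <- vapply(totals, function(k) {
      if (k == 0) integer(n_fov)
      else as.integer(rmultinom(1, k, rep(1 / n_fov, n_fov)))
    }, integer(n_fov))
    if (n_fov == 1L) alloc <- matrix(as.integer(totals), 1L, 4L,
                                     dimnames = list(NULL, names(totals)))
    fov_seeds <- sample.int(.Machine$integer.max - 1L, n_fov)

    ncol_grid <- ceiling(sqrt(n_fov))
    images <- vector("list", n_fov)
    truth_list <- vector("list", n_fov)
    for (f in seq_len(n_fov)) {
      fspec <- spec
      fspec$n_cmc <- alloc[f, "CMC"]; fspec$n_leuko <- alloc[f, "leukocyte"]
      fspec$n_dual <- alloc[f, "dual"]; fspec$n_debris <- alloc[f, "debris"]
      # a single-FOV slide is exactly make_fov(spec) with the slide totals
      fspec$seed <- if (n_fov == 1L) spec$seed else fov_seeds[f]
      gp <- c((f - 1L) %/% ncol_grid + 1L, (f - 1L) %% ncol_grid + 1L)
      if (render) {
        scene <- make_fov(fspec, fov_index = f, grid_pos = gp)
        images[[f]] <- scene$image
        tr <- scene$truth
      } else {
        k <- sum(alloc[f, ])
        cls <- rep(colnames(alloc), alloc[f, ])
        tr <- data.frame(
          object_id = seq_len(k), class = cls,
          centroid_row = rep(NA_real_, k), centroid_col = rep(NA_real_, k),
          nucleus = cls != "debris",
          pattern = rep(NA_character_, k), radius = rep(NA_real_, k),
          stringsAsFactors = FALSE)
      }
      if (nrow(tr)) tr$fov <- f
      truth_list[[f]] <- tr
    }
    truth <- do.call(rbind, truth_list[vapply(truth_list, nrow, 0L) > 0])
    if (is.null(truth))
      truth <- cbind(truth_list[[1]][0, , drop = FALSE],
                     fov = integer(0))
    structure(list(images = if (render) images else list(),
                   truth = truth, n_fov = n_fov, fov_counts = alloc,
                   spec = spec),
              class = "slide_image_set")
  })
}

#' @export
print.slide_image_set <- function(x, ...) {
  tot <- table(factor(x$truth$class,
                      c("CMC", "leukocyte", "dual", "debris")))
  cat(sprintf("<slide_image_set> %d FOVs; truth totals: %s\n", x$n_fov,
              paste(names(tot), tot, sep = "=", collapse = ", ")))
  invisible(x)
}
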