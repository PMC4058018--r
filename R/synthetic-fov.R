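#' Scene specification for a synthetic field of view
#'
#' Describes one cytospin field of view (FOV) to be rendered by [make_fov()]:
#' how many objects of each class it contains and how they look. Object
#' classes mirror what is seen on a stained CD45-depleted blood slide:
#' CMCs (DAPI nucleus + green marker cytoplasm, no red), leukocytes (nucleus +
#' red CD45), dual-positive cells (nucleus + red + green), and anuclear
#' debris (irregular green and/or red blobs).
#'
#' @param fov_shape integer(2), image size in pixels (rows, cols).
#' @param n_cmc,n_leuko,n_dual,n_debris non-negative object counts.
#' @param nucleus_radius_range numeric(2), min/max nucleus radius in pixels.
#' @param margin_sharpness positive scalar; the rendered DAPI image is
#'   smoothed with a Gaussian of sigma = 1/margin_sharpness, so large values
#'   give the sharp, well-defined nuclear margin required of a countable
#'   cell and small values give fuzzy margins that the margin filter should
#'   reject.
#' @param pattern green staining pattern: `"uniform"` or `"punctate"`
#'   cytoplasmic (Melan-A-like), or `"nuclear_cytoplasmic"` (S100B-like,
#'   green over both the cytoplasm and the nucleus).
#' @param background_mean,background_sd Gaussian background intensity on the
#'   0-255 scale, added to every channel.
#' @param cell_regime `"patient"` (CMC nuclei drawn from the same size
#'   distribution as leukocytes) or `"cell_line"` (CMC/dual nuclei enlarged
#'   1.6x, as cultured melanoma cells are visibly larger than leukocytes).
#' @param cyto_width cytoplasm ring width in pixels beyond the nucleus.
#' @param seed integer seed; a given spec always renders the same image.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(fov_shape = c(256L, 256L),
                       n_cmc = 0L, n_leuko = 0L, n_dual = 0L, n_debris = 0L,
                       nucleus_radius_range = c(6, 11),
                       margin_sharpness = 4,
                       pattern = c("uniform", "punctate", "nuclear_cytoplasmic"),
                       background_mean = 8, background_sd = 3,
                       cell_regime = c("patient", "cell_line"),
                       cyto_width = 4,
                       seed = 1L) {
  pattern <- match.arg(pattern)
  cell_regime <- match.arg(cell_regime)
  counts <- c(n_cmc = n_cmc, n_leuko = n_leuko, n_dual = n_dual,
              n_debris = n_debris)
  if (!all(vapply(counts, is_count, logical(1))))
    stopf("object counts must be non-negative integers")
  if (length(fov_shape) != 2L || any(fov_shape < 32))
    stopf("fov_shape must be two pixel dimensions >= 32")
  if (length(nucleus_radius_range) != 2L || any(nucleus_radius_range <= 0) ||
      diff(nucleus_radius_range) < 0)
    stopf("nucleus_radius_range must be increasing and positive")
  if (!is.numeric(margin_sharpness) || margin_sharpness <= 0)
    stopf("margin_sharpness must be > 0")
  if (background_mean < 0 || background_mean > 255 || background_sd < 0)
    stopf("background must have mean in [0,255] and sd >= 0")
  structure(list(
    fov_shape = as.integer(fov_shape),
    n_cmc = as.integer(n_cmc), n_leuko = as.integer(n_leuko),
    n_dual = as.integer(n_dual), n_debris = as.integer(n_debris),
    nucleus_radius_range = as.numeric(nucleus_radius_range),
    margin_sharpness = margin_sharpness, pattern = pattern,
    background_mean = background_mean, background_sd = background_sd,
    cell_regime = cell_regime, cyto_width = cyto_width,
    seed = as.integer(seed)), class = "scene_spec")
}

# intensity constants for rendered structures (0-255 scale)
.render_int <- list(dapi = 200, green = 140, red = 150,
                    punctate_base = 25, punctate_focus = 230,
                    n_foci = 8, focus_radius = 1.5)

# elliptical mask on a local patch; returns patch row/col ranges + logical mask
.ellipse_patch <- function(shape, cr, cc, a, b, theta) {
  ext <- ceiling(max(a, b)) + 1L
  r0 <- max(1L, floor(cr - ext)); r1 <- min(shape[1], ceiling(cr + ext))
  c0 <- max(1L, floor(cc - ext)); c1 <- min(shape[2], ceiling(cc + ext))
  dr <- (r0:r1) - cr; dc <- (c0:c1) - cc
  u <- outer(dr, dc, function(x, y) x * cos(theta) + y * sin(theta))
  v <- outer(dr, dc, function(x, y) -x * sin(theta) + y * cos(theta))
  list(r = r0:r1, c = c0:c1, mask = (u / a)^2 + (v / b)^2 <= 1)
}

.paint <- function(canvas, patch, value) {
  sub <- canvas[patch$r, patch$c, drop = FALSE]
  sub[patch$mask] <- pmax(sub[patch$mask], value)
  canvas[patch$r, patch$c] <- sub
  canvas
}

#' Render one synthetic field of view with ground truth
#'
#' Places the requested objects without overlap (rejection sampling, up to
#' 1000 attempts per object), renders the three channels as 8-bit images and
#' returns them together with a per-object ground-truth table. CMCs have a
#' DAPI nucleus, green cytoplasm in the requested pattern and no red;
#' leukocytes a nucleus and red cytoplasm; dual-positive cells red and green;
#' debris irregular green and/or red blobs with no nucleus. Identical specs
#' render bit-identical images.
#'
#' @param spec a [scene_spec()].
#' @param fov_index integer page index attached to the result.
#' @param grid_pos integer(2) grid position attached to the result.
#' @return A list of class `fov_scene` with elements `image` (class
#'   `fov_image`: `channels` list of integer matrices `dapi`, `red`, `green`,
#'   plus `fov_index`, `grid_pos`) and `truth` (data.frame: `object_id`,
#'   `class`, `centroid_row`, `centroid_col`, `nucleus`, `pattern`,
#'   `radius`).
#' @export
make_fov <- function(spec, fov_index = 1L, grid_pos = c(1L, 1L)) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, .make_fov_impl(spec, fov_index, grid_pos))
}

.make_fov_impl <- function(spec, fov_index, grid_pos) {
  shape <- spec$fov_shape
  classes <- rep(c("CMC", "leukocyte", "dual", "debris"),
                 c(spec$n_cmc, spec$n_leuko, spec$n_dual, spec$n_debris))
  n <- length(classes)
  dapi <- matrix(0, shape[1], shape[2])
  red <- matrix(0, shape[1], shape[2])
  green <- matrix(0, shape[1], shape[2])

  # geometry draws
  rr <- spec$nucleus_radius_range
  radius <- if (n) runif(n, rr[1], rr[2]) else numeric(0)
  enlarged <- spec$cell_regime == "cell_line" & classes %in% c("CMC", "dual")
  radius[enlarged] <- radius[enlarged] * 1.6
  axis_q <- if (n) runif(n, 1, 1.3) else numeric(0)  # nucleus axis ratio
  theta <- if (n) runif(n, 0, pi) else numeric(0)
  ext <- radius * sqrt(axis_q) + spec$cyto_width  # outer footprint radius
  ext[classes == "debris"] <- radius[classes == "debris"] * 1.6

  # non-overlapping placement by rejection sampling
  cr <- numeric(n); cc <- numeric(n)
  for (i in seq_len(n)) {
    margin <- ext[i] + 3
    if (2 * margin >= min(shape))
      stopf("FOV %dx%d too small to place object %d (%s)",
            shape[1], shape[2], i, classes[i])
    placed <- FALSE
    for (attempt in 1:1000) {
      y <- runif(1, margin, shape[1] - margin)
      x <- runif(1, margin, shape[2] - margin)
      if (i == 1L || all(sqrt((cr[seq_len(i - 1)] - y)^2 +
                              (cc[seq_len(i - 1)] - x)^2) >
                         ext[seq_len(i - 1)] + ext[i] + 2)) {
        cr[i] <- y; cc[i] <- x; placed <- TRUE; break
      }
    }
    if (!placed)
      stopf(paste0("could not place object %d of %d (class %s) without ",
                   "overlap after 1000 attempts; reduce counts or enlarge ",
                   "the FOV"), i, n, classes[i])
  }

  ints <- .render_int
  for (i in seq_len(n)) {
    a <- radius[i] * sqrt(axis_q[i]); b <- radius[i] / sqrt(axis_q[i])
    if (classes[i] == "debris") {
      # irregular anuclear blob: union of a few offset ellipses
      chan <- sample(c("green", "red", "both"), 1, prob = c(.5, .25, .25))
      for (k in seq_len(sample(3:6, 1))) {
        dy <- runif(1, -radius[i], radius[i]); dx <- runif(1, -radius[i], radius[i])
        p <- .ellipse_patch(shape, cr[i] + dy, cc[i] + dx,
                            runif(1, 2, 5), runif(1, 2, 5), runif(1, 0, pi))
        val <- runif(1, 120, 200)
        if (chan %in% c("green", "both")) green <- .paint(green, p, val)
        if (chan %in% c("red", "both")) red <- .paint(red, p, val)
      }
      next
    }
    nuc <- .ellipse_patch(shape, cr[i], cc[i], a, b, theta[i])
    dapi <- .paint(dapi, nuc, min(255, ints$dapi + rnorm(1, 0, 12)))
    ring_out <- .ellipse_patch(shape, cr[i], cc[i],
                               a + spec$cyto_width, b + spec$cyto_width,
                               theta[i])
    # ring mask on the outer patch: outer ellipse minus nucleus ellipse
    dr <- ring_out$r - cr[i]; dc <- ring_out$c - cc[i]
    u <- outer(dr, dc, function(x, y) x * cos(theta[i]) + y * sin(theta[i]))
    v <- outer(dr, dc, function(x, y) -x * sin(theta[i]) + y * cos(theta[i]))
    inner <- (u / a)^2 + (v / b)^2 <= 1
    ring <- ring_out; ring$mask <- ring_out$mask & !inner

    if (classes[i] %in% c("leukocyte", "dual"))
      red <- .paint(red, ring, min(255, ints$red + rnorm(1, 0, 10)))
    if (classes[i] %in% c("CMC", "dual")) {
      gval <- min(255, ints$green + rnorm(1, 0, 10))
      if (spec$pattern == "punctate") {
        green <- .paint(green, ring, ints$punctate_base)
        pix <- which(ring$mask, arr.ind = TRUE)
        if (nrow(pix)) {
          idx <- sample.int(nrow(pix), min(ints$n_foci, nrow(pix)))
          for (j in idx) {
            p <- .ellipse_patch(shape, ring$r[pix[j, 1]], ring$c[pix[j, 2]],
                                ints$focus_radius, ints$focus_radius, 0)
            green <- .paint(green, p, ints$punctate_focus)
          }
        }
      } else {
        green <- .paint(green, ring, gval)
        if (spec$pattern == "nuclear_cytoplasmic")
          green <- .paint(green, nuc, gval * 0.85)
      }
    }
  }

  sigma_dapi <- 1 / spec$margin_sharpness
  if (sigma_dapi >= 0.3) dapi <- EBImage::gblur(dapi, sigma = sigma_dapi)
  red <- EBImage::gblur(red, sigma = 0.7)
  green <- EBImage::gblur(green, sigma = 0.7)

  finish <- function(ch) {
    ch <- ch + rnorm(length(ch), spec$background_mean, spec$background_sd)
    matrix(as.integer(pmin(255, pmax(0, round(ch)))), shape[1], shape[2])
  }
  image <- structure(list(
    channels = list(dapi = finish(dapi), red = finish(red),
                    green = finish(green)),
    fov_index = as.integer(fov_index),
    grid_pos = as.integer(grid_pos)), class = "fov_image")

  truth <- data.frame(
    object_id = seq_len(n), class = classes,
    centroid_row = cr, centroid_col = cc,
    nucleus = classes != "debris",
    pattern = ifelse(classes %in% c("CMC", "dual"), spec$pattern, NA_character_),
    radius = radius, stringsAsFactors = FALSE)
  if (n == 0L)
    truth <- truth[0, , drop = FALSE]
  structure(list(image = image, truth = truth), class = "fov_scene")
}

#' @export
print.fov_image <- function(x, ...) {
  cat(sprintf("<fov_image> %d x %d px, fov %d, grid (%d,%d)\n",
              nrow(x$channels$dapi), ncol(x$channels$dapi),
              x$fov_index, x$grid_pos[1], x$grid_pos[2]))
  invisible(x)
}
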