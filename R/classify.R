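#' Counting configuration
#'
#' All tunable cut-offs of the counting algorithm, validated and bundled.
#' Unknown arguments are rejected.
#'
#' @param min_area,max_area nuclear area window in px^2.
#' @param ar_max maximum nuclear aspect ratio.
#' @param circ_min minimum nuclear circularity (`4*pi*A/P^2`, clamped to 1).
#' @param margin_min minimum nuclear margin score (boundary gradient /
#'   interior intensity); enforces the well-defined-margin rule.
#' @param annulus_width cytoplasmic annulus width in px.
#' @param green_cv_cut per-pixel CV of annulus green separating uniform
#'   (below) from punctate (above) staining.
#' @param stringency green-threshold bias factor for patient/control modes.
#' @param mode default threshold mode (`"patient"`, `"control"`,
#'   `"explicit"`).
#' @param marker melanoma marker on the green channel: `"MelanA"`
#'   (cytoplasmic staining required) or `"S100B"` (cytoplasmic and/or
#'   nuclear accepted).
#' @param debris_min_area minimum area (px^2) of an anuclear green/red blob
#'   tallied as debris.
#' @return List of class `count_config`.
#' @export
count_config <- function(min_area = 30, max_area = 5000, ar_max = 2.5,
                         circ_min = 0.6, margin_min = 0.15,
                         annulus_width = 4, green_cv_cut = 0.6,
                         stringency = 1.25,
                         mode = c("patient", "control", "explicit"),
                         marker = c("MelanA", "S100B"),
                         debris_min_area = 20) {
  mode <- match.arg(mode); marker <- match.arg(marker)
  if (min_area <= 0 || max_area <= min_area)
    stopf("need 0 < min_area < max_area")
  if (ar_max < 1) stopf("ar_max must be >= 1")
  if (circ_min < 0 || circ_min > 1) stopf("circ_min must be in [0,1]")
  if (margin_min < 0) stopf("margin_min must be >= 0")
  if (!is_count(annulus_width) || annulus_width < 1)
    stopf("annulus_width must be a count >= 1")
  if (green_cv_cut <= 0) stopf("green_cv_cut must be > 0")
  if (stringency <= 1) stopf("stringency must be > 1")
  if (debris_min_area < 1) stopf("debris_min_area must be >= 1")
  structure(list(min_area = min_area, max_area = max_area, ar_max = ar_max,
                 circ_min = circ_min, margin_min = margin_min,
                 annulus_width = as.integer(annulus_width),
                 green_cv_cut = green_cv_cut, stringency = stringency,
                 mode = mode, marker = marker,
                 debris_min_area = debris_min_area),
            class = "count_config")
}

#' Classify measured cells into the four object classes
#'
#' Applies the CMC decision rules to a measured-cell table. A cell is
#' counted as a CMC only if all of the following hold: (P1) it has a
#' nucleus with a well-defined margin (`margin_score >= margin_min`);
#' (P2) its green signal exceeds the green threshold; (P3) its staining
#' pattern is consistent with the marker - for Melan-A the green must be
#' predominantly cytoplasmic (annulus mean above nuclear mean), in either a
#' uniform or punctate pattern, while S100B also accepts nuclear green;
#' (N1) its red signal does not exceed the red threshold - a green+red cell
#' is `dual` ("yellow") and is never counted as a CMC, a red-only cell is a
#' `leukocyte`; (N2) it is not debris (anuclear objects, labelled `debris`);
#' (N3) it does not touch the FOV border (`border`). Cell size is
#' deliberately not a criterion: patient CMCs can be as small as
#' leukocytes. Green-positive cells failing P1 or P3 fall into `null`, as
#' do cells negative in both channels.
#'
#' @param cells data.frame from [measure_cells()] (columns `green_mean`,
#'   `red_mean`, `green_nuclear_mean`, `margin_score`, `border`,
#'   `nucleus_present`).
#' @param thresholds a `threshold_pair` from [select_thresholds()].
#' @param config a [count_config()] (supplies `marker` and `margin_min`).
#' @return factor of class labels with levels
#'   `CMC, leukocyte, dual, null, debris, border`.
#' @export
classify_cells <- function(cells, thresholds, config = count_config()) {
  stopifnot(inherits(thresholds, "threshold_pair"),
            inherits(config, "count_config"))
  n <- nrow(cells)
  lv <- c("CMC", "leukocyte", "dual", "null", "debris", "border")
  if (n == 0L) return(factor(character(0), levels = lv))
  nucleus <- if ("nucleus_present" %in% names(cells)) cells$nucleus_present
             else rep(TRUE, n)
  border <- if ("border" %in% names(cells)) cells$border else rep(FALSE, n)
  margin_ok <- cells$margin_score >= config$margin_min
  green_pos <- cells$green_mean > thresholds$t_green
  red_pos <- cells$red_mean > thresholds$t_red
  pattern_ok <- if (config$marker == "MelanA")
    cells$green_mean > cells$green_nuclear_mean
  else rep(TRUE, n)

  out <- rep("null", n)
  out[red_pos & !green_pos] <- "leukocyte"
  out[red_pos & green_pos] <- "dual"
  out[green_pos & !red_pos & nucleus & margin_ok & pattern_ok] <- "CMC"
  out[!nucleus] <- "debris"
  out[border] <- "border"
  factor(out, levels = lv)
}

# anuclear debris blobs in one FOV: connected green-or-red components that
# do not meet any (dilated) nuclear mask and are at least debris_min_area.
# Blob segmentation uses a robust per-channel background cut (median +
# 5 MAD) rather than the per-cell scatter thresholds, which can sit inside
# the background noise on marker-negative slides.
.count_debris_fov <- function(fov, labels, config) {
  bg_cut <- function(ch) {
    v <- as.numeric(ch)
    stats::median(v) + 5 * stats::mad(v)
  }
  sig <- fov$channels$green > bg_cut(fov$channels$green) |
    fov$channels$red > bg_cut(fov$channels$red)
  blob <- label8(sig)
  if (max(blob) == 0L) return(0L)
  brush <- EBImage::makeBrush(2L * config$annulus_width + 1L, shape = "disc")
  near_nuc <- EBImage::dilate((labels > 0) * 1, brush) > 0
  blob_v <- as.vector(blob)
  touched <- unique(blob_v[blob_v > 0 & as.vector(near_nuc)])
  sizes <- tabulate(blob_v[blob_v > 0], max(blob))
  sum(sizes >= config$debris_min_area &
        !(seq_along(sizes) %in% touched))
}

#' Count a whole slide
#'
#' Runs the full counting algorithm over every FOV of a slide: nuclear
#' segmentation ([nuclear_mask()]), per-cell measurement
#' ([measure_cells()]), global threshold selection over the pooled per-cell
#' intensity distributions ([select_thresholds()], unless `thresholds` is
#' supplied), classification ([classify_cells()]) and tallying into the
#' four object classes - green (CMCs), red (leukocytes), yellow (dual) and
#' null - with anuclear debris blobs and border-touching cells tallied
#' separately. Optionally writes one RGB overlay PNG per FOV with
#' class-coded outlines for manual review.
#'
#' @param slide a `slide_image_set`.
#' @param config a [count_config()].
#' @param thresholds optional explicit `threshold_pair`; by default derived
#'   from the slide in `config$mode`.
#' @param overlay_dir directory for per-FOV overlay PNGs, or `NULL` to skip.
#' @return List of class `slide_count`: `tally` (named counts `n_cmc`,
#'   `n_leuko`, `n_dual`, `n_null`, `n_debris`, `n_border`), `cv_percent`
#'   (Poisson CV of the CMC tally, `NA` when zero), `cells` (per-object
#'   table with `class` column), `thresholds`, `config`.
#' @export
count_slide <- function(slide, config = count_config(), thresholds = NULL,
                        overlay_dir = NULL) {
  stopifnot(inherits(slide, "slide_image_set"),
            inherits(config, "count_config"))
  if (!length(slide$images)) stopf("slide has no rendered images")

  per_fov <- vector("list", length(slide$images))
  masks <- vector("list", length(slide$images))
  for (f in seq_along(slide$images)) {
    fov <- slide$images[[f]]
    res <- tryCatch({
      nm <- nuclear_mask(fov$channels$dapi, config)
      list(cells = measure_cells(fov, nm$objects, nm$labels, config),
           labels = nm$labels)
    }, error = function(e)
      stopf("FOV %d: %s", fov$fov_index, conditionMessage(e)))
    per_fov[[f]] <- res$cells
    masks[[f]] <- res$labels
  }
  cells <- do.call(rbind, per_fov)

  if (is.null(thresholds)) {
    if (nrow(cells) == 0L)
      # nothing nucleated to derive thresholds from: report an empty slide
      # (signal classes unassessed; pass explicit thresholds to scan an
      # all-debris slide for blobs)
      thresholds <- structure(list(t_red = 255, t_green = 255,
                                   mode = "explicit"),
                              class = "threshold_pair")
    else
      thresholds <- select_thresholds(cells, mode = config$mode,
                                      stringency = config$stringency)
  }
  cells$class <- classify_cells(cells, thresholds, config)

  n_debris_blobs <- 0L
  for (f in seq_along(slide$images))
    n_debris_blobs <- n_debris_blobs +
      .count_debris_fov(slide$images[[f]], masks[[f]], config)

  tal <- table(cells$class)
  tally <- c(n_cmc = unname(tal[["CMC"]]), n_leuko = unname(tal[["leukocyte"]]),
             n_dual = unname(tal[["dual"]]), n_null = unname(tal[["null"]]),
             n_debris = unname(tal[["debris"]]) + n_debris_blobs,
             n_border = unname(tal[["border"]]))

  if (!is.null(overlay_dir))
    .write_overlays(slide, masks, cells, overlay_dir)

  structure(list(
    tally = tally,
    cv_percent = if (tally[["n_cmc"]] >= 1) poisson_cv(tally[["n_cmc"]])
                 else NA_real_,
    cells = cells, thresholds = thresholds, config = config),
    class = "slide_count")
}

#' @export
print.slide_count <- function(x, ...) {
  cat("<slide_count>\n")
  cat(sprintf("  CMC (green):     %d%s\n", x$tally[["n_cmc"]],
              if (!is.na(x$cv_percent))
                sprintf("  (Poisson CV %.3g%%)", x$cv_percent) else ""))
  cat(sprintf("  leukocyte (red): %d\n", x$tally[["n_leuko"]]))
  cat(sprintf("  dual (yellow):   %d\n", x$tally[["n_dual"]]))
  cat(sprintf("  null:            %d\n", x$tally[["n_null"]]))
  cat(sprintf("  debris: %d, border-excluded: %d\n",
              x$tally[["n_debris"]], x$tally[["n_border"]]))
  cat(sprintf("  thresholds: t_red %.1f, t_green %.1f (%s)\n",
              x$thresholds$t_red, x$thresholds$t_green, x$thresholds$mode))
  invisible(x)
}

# RGB overlays: merged channels with class-coded object outlines
.write_overlays <- function(slide, masks, cells, overlay_dir) {
  dir.create(overlay_dir, showWarnings = FALSE, recursive = TRUE)
  cols <- list(CMC = c(1, 1, 1), leukocyte = c(1, 0.3, 0.3),
               dual = c(1, 1, 0), null = c(0.6, 0.6, 0.6),
               debris = c(1, 0, 1), border = c(0, 0.8, 1))
  for (f in seq_along(slide$images)) {
    fov <- slide$images[[f]]
    rgb <- array(0, dim = c(nrow(masks[[f]]), ncol(masks[[f]]), 3))
    rgb[, , 1] <- fov$channels$red / 255
    rgb[, , 2] <- fov$channels$green / 255
    rgb[, , 3] <- fov$channels$dapi / 255
    bnd <- .boundary_mask(masks[[f]])
    fc <- cells[cells$fov == fov$fov_index, , drop = FALSE]
    for (i in seq_len(nrow(fc))) {
      sel <- bnd & masks[[f]] == fc$label[i]
      col <- cols[[as.character(fc$class[i])]]
      for (k in 1:3) {
        plane <- rgb[, , k]; plane[sel] <- col[k]; rgb[, , k] <- plane
      }
    }
    png::writePNG(rgb, file.path(overlay_dir,
                                 sprintf("fov_%03d.png", fov$fov_index)))
  }
  invisible(NULL)
}
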