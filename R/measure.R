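#' Measure per-cell intensities and staining-pattern features
#'
#' For each accepted nucleus, intensities are measured over a cytoplasmic
#' annulus obtained by dilating the nuclear mask by `annulus_width` pixels
#' (disc structuring element) and removing all nuclear pixels (of any cell):
#' `green_mean` and `red_mean` are annulus means, `green_nuclear_mean` is
#' the green mean over the nucleus itself, and `green_cv` (annulus sd /
#' annulus mean of green; 0 when the mean is 0) separates punctate from
#' uniform cytoplasmic staining. Nuclei whose annulus would extend beyond
#' the image are flagged `border = TRUE` and later excluded from tallies.
#'
#' @param fov a `fov_image`.
#' @param nuclei data.frame of accepted nuclei from [nuclear_mask()].
#' @param labels nuclear label matrix from [nuclear_mask()].
#' @param config a [count_config()] (supplies `annulus_width`).
#' @return data.frame: one row per nucleus with the nucleus shape columns
#'   plus `green_mean`, `red_mean`, `green_nuclear_mean`, `green_cv`,
#'   `border`, `nucleus_present` (always TRUE here) and `fov`.
#' @export
measure_cells <- function(fov, nuclei, labels, config = count_config()) {
  stopifnot(inherits(fov, "fov_image"), inherits(config, "count_config"))
  w <- config$annulus_width
  nr <- nrow(labels); nc <- ncol(labels)
  green <- fov$channels$green; red <- fov$channels$red
  brush <- EBImage::makeBrush(2L * as.integer(w) + 1L, shape = "disc")

  meas <- lapply(seq_len(nrow(nuclei)), function(i) {
    lbl <- nuclei$label[i]
    pix <- which(labels == lbl, arr.ind = TRUE)
    r0 <- min(pix[, 1]) - w - 1L; r1 <- max(pix[, 1]) + w + 1L
    c0 <- min(pix[, 2]) - w - 1L; c1 <- max(pix[, 2]) + w + 1L
    border <- r0 < 1L || c0 < 1L || r1 > nr || c1 > nc
    rs <- max(1L, r0):min(nr, r1); cs <- max(1L, c0):min(nc, c1)
    lab_crop <- labels[rs, cs, drop = FALSE]
    mask <- lab_crop == lbl
    dil <- EBImage::dilate(mask * 1, brush) > 0
    annulus <- dil & lab_crop == 0L
    g_ann <- green[rs, cs, drop = FALSE][annulus]
    r_ann <- red[rs, cs, drop = FALSE][annulus]
    g_nuc <- green[rs, cs, drop = FALSE][mask]
    g_mean <- if (length(g_ann)) mean(g_ann) else 0
    g_cv <- if (g_mean > 0 && length(g_ann) > 1) sd(g_ann) / g_mean else 0
    data.frame(green_mean = g_mean,
               red_mean = if (length(r_ann)) mean(r_ann) else 0,
               green_nuclear_mean = mean(g_nuc),
               green_cv = g_cv, border = border)
  })
  out <- cbind(nuclei,
               if (length(meas)) do.call(rbind, meas)
               else data.frame(green_mean = numeric(0), red_mean = numeric(0),
                               green_nuclear_mean = numeric(0),
                               green_cv = numeric(0), border = logical(0)))
  out$nucleus_present <- rep(TRUE, nrow(out))
  out$fov <- rep(fov$fov_index, nrow(out))
  rownames(out) <- NULL
  out
}
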