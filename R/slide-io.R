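#' Write a slide image set to disk
#'
#' Writes one 8-bit multi-page TIFF per channel (`dapi.tif`, `red.tif`,
#' `green.tif`, one page per FOV), the ground-truth table (`truth.csv`, when
#' present) and a small `slide.yml` channel map / metadata file.
#'
#' @param slide a `slide_image_set` from [make_slide()] (or [read_slide()]).
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_slide <- function(slide, dir) {
  stopifnot(inherits(slide, "slide_image_set"))
  if (!length(slide$images)) stopf("slide has no rendered images to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- c("dapi", "red", "green")
  for (ch in channels) {
    pages <- lapply(slide$images, function(im) im$channels[[ch]] / 255)
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 8L)
  }
  if (!is.null(slide$truth) && nrow(slide$truth))
    write.csv(slide$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    channels = list(dapi = "dapi.tif", red = "red.tif", green = "green.tif"),
    n_fov = slide$n_fov,
    fov_shape = dim(slide$images[[1]]$channels$dapi)),
    file.path(dir, "slide.yml"))
  invisible(dir)
}

#' Read a slide image set from disk
#'
#' Reads the per-channel multi-page 8-bit TIFF stacks written by
#' [write_slide()] (or produced by a microscope export following the same
#' layout). Fails loudly on a missing channel, on page-count or shape
#' mismatches between channels, and on non-8-bit data.
#'
#' @param dir directory containing `slide.yml` (or the default
#'   `dapi.tif`/`red.tif`/`green.tif` files).
#' @return A `slide_image_set` (with `truth` attached when `truth.csv`
#'   exists).
#' @export
read_slide <- function(dir) {
  if (!dir.exists(dir)) stopf("slide directory not found: %s", dir)
  meta_path <- file.path(dir, "slide.yml")
  chmap <- if (file.exists(meta_path))
    yaml::read_yaml(meta_path)$channels
  else list(dapi = "dapi.tif", red = "red.tif", green = "green.tif")
  for (ch in c("dapi", "red", "green"))
    if (is.null(chmap[[ch]]))
      stopf("channel map in %s is missing channel '%s'", meta_path, ch)

  stacks <- lapply(c(dapi = "dapi", red = "red", green = "green"), function(ch) {
    path <- file.path(dir, chmap[[ch]])
    if (!file.exists(path))
      stopf("missing channel '%s': file not found: %s", ch, path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    for (p in pages) {
      bits <- attr(p, "bits.per.sample")
      if (!is.null(bits) && bits != 8L)
        stopf(paste0("channel '%s' in %s is %d-bit; this pipeline analyses ",
                     "8-bit (0-255) images - rescale the stack to 8 bits ",
                     "before reading"), ch, path, bits)
      if (max(p) > 255L)
        stopf("channel '%s' in %s has intensities above 255 (not 8-bit)",
              ch, path)
      if (length(dim(p)) != 2L)
        stopf("channel '%s' in %s is not single-sample greyscale", ch, path)
    }
    pages
  })

  n_pages <- vapply(stacks, length, 0L)
  if (length(unique(n_pages)) != 1L)
    stopf("page-count mismatch between channels: dapi=%d, red=%d, green=%d",
          n_pages[["dapi"]], n_pages[["red"]], n_pages[["green"]])
  shapes <- lapply(stacks, function(s) dim(s[[1]]))
  if (length(unique(shapes)) != 1L)
    stopf("channel image shapes differ between stacks")

  n_fov <- n_pages[[1]]
  ncol_grid <- ceiling(sqrt(n_fov))
  images <- lapply(seq_len(n_fov), function(f) {
    structure(list(
      channels = list(
        dapi = matrix(as.integer(stacks$dapi[[f]]), nrow(stacks$dapi[[f]])),
        red = matrix(as.integer(stacks$red[[f]]), nrow(stacks$red[[f]])),
        green = matrix(as.integer(stacks$green[[f]]), nrow(stacks$green[[f]]))),
      fov_index = f,
      grid_pos = c((f - 1L) %/% ncol_grid + 1L, (f - 1L) %% ncol_grid + 1L)),
      class = "fov_image")
  })
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  structure(list(images = images, truth = truth, n_fov = n_fov,
                 fov_counts = NULL, spec = NULL),
            class = "slide_image_set")
}
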