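# 8-connected component labeling: EBImage::bwlabel is 4-connected, so merge
# labels that touch only diagonally (union-find over diagonal adjacencies).
label8 <- function(bw) {
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(bw), ncol(bw))
  n <- max(lab)
  if (n < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]   # \ diagonal
  a2 <- lab[-1, -nc]; b2 <- lab[-nr, -1]   # / diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, 0L)
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  # relabel consecutively in raster order of first appearance
  u <- unique(lab[lab > 0])
  remap <- integer(max(u)); remap[u] <- seq_along(u)
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Shape metrics of a single binary object
#'
#' Area, perimeter (boundary-pixel estimator), aspect ratio (major/minor
#' axis of the intensity-moment ellipse) and circularity
#' `4 * pi * area / perimeter^2`, clamped to at most 1 (digital perimeter
#' estimates can push the raw ratio slightly above 1 for near-circular
#' objects).
#'
#' @param mask logical or 0/1 matrix containing one connected object.
#' @return List with `area`, `perimeter`, `aspect_ratio`, `circularity`.
#' @export
shape_metrics <- function(mask) {
  m <- (mask > 0) * 1
  if (sum(m) == 0) stopf("empty mask: no object pixels")
  fs <- EBImage::computeFeatures.shape(m)
  fm <- EBImage::computeFeatures.moment(m)
  area <- fs[1, "s.area"]; per <- fs[1, "s.perimeter"]
  ecc <- fm[1, "m.eccentricity"]
  ar <- if (is.na(ecc)) 1 else 1 / sqrt(1 - min(ecc, 0.999999)^2)
  circ <- if (per > 0) min(1, 4 * pi * area / per^2) else 1
  list(area = as.numeric(area), perimeter = as.numeric(per),
       aspect_ratio = as.numeric(ar), circularity = as.numeric(circ))
}

# central-difference gradient magnitude with replicated edges
.grad_mag <- function(img) {
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1, seq_len(nr - 1)), ]; down <- img[c(seq_len(nr - 1) + 1, nr), ]
  left <- img[, c(1, seq_len(nc - 1))]; right <- img[, c(seq_len(nc - 1) + 1, nc)]
  sqrt(((down - up) / 2)^2 + ((right - left) / 2)^2)
}

# boundary pixels of each labeled object: object pixels with a 4-neighbour
# outside the object
.boundary_mask <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  up <- lab[c(1, seq_len(nr - 1)), ]; down <- lab[c(seq_len(nr - 1) + 1, nr), ]
  left <- lab[, c(1, seq_len(nc - 1))]; right <- lab[, c(seq_len(nc - 1) + 1, nc)]
  lab > 0 & (up != lab | down != lab | left != lab | right != lab)
}

#' Segment nuclei from the DAPI channel
#'
#' Thresholds the DAPI channel with [isodata_threshold()], labels
#' 8-connected components, and keeps components passing the morphological
#' filters: area within `[min_area, max_area]`, aspect ratio at most
#' `ar_max`, circularity at least `circ_min`, and margin score at least
#' `margin_min`. The margin score quantifies how well-defined the nuclear
#' margin is - mean gradient magnitude over the object boundary divided by
#' mean interior intensity - so fuzzy, out-of-focus nuclei score low and are
#' dropped.
#'
#' @param dapi integer matrix (0-255), the DAPI channel of one FOV.
#' @param config a [count_config()] supplying the filter cut-offs.
#' @return List: `objects` (data.frame of accepted nuclei: `label`, `area`,
#'   `perimeter`, `centroid_row`, `centroid_col`, `aspect_ratio`,
#'   `circularity`, `margin_score`), `labels` (full label matrix including
#'   rejected components), `threshold` (DAPI isodata threshold) and
#'   `n_candidates` (components before filtering). A blank image (single
#'   intensity level) yields an empty object list without error only when
#'   there is background variation; a strictly constant image raises the
#'   degenerate-histogram error from [isodata_threshold()].
#' @export
nuclear_mask <- function(dapi, config = count_config()) {
  stopifnot(inherits(config, "count_config"))
  t_dapi <- isodata_threshold(dapi)
  lab <- label8(dapi > t_dapi)
  n <- max(lab)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), aspect_ratio = numeric(0),
                      circularity = numeric(0), margin_score = numeric(0))
  if (n == 0L)
    return(list(objects = empty, labels = lab, threshold = t_dapi,
                n_candidates = 0L))

  fs <- EBImage::computeFeatures.shape(lab)
  fm <- EBImage::computeFeatures.moment(lab)
  area <- fs[, "s.area"]; per <- fs[, "s.perimeter"]
  ecc <- pmin(fm[, "m.eccentricity"], 0.999999)
  ar <- ifelse(is.na(ecc), 1, 1 / sqrt(1 - ecc^2))
  circ <- ifelse(per > 0, pmin(1, 4 * pi * area / per^2), 1)

  grad <- .grad_mag(dapi)
  bnd <- .boundary_mask(lab)
  num <- as.numeric(dapi)
  lab_v <- as.vector(lab); bnd_v <- as.vector(bnd)
  sum_by <- function(vals, labs) {  # per-label sums over 1..n
    out <- numeric(n)
    if (length(labs)) {
      agg <- rowsum(vals, labs)
      out[as.integer(rownames(agg))] <- agg
    }
    out
  }
  mean_bnd_grad <- sum_by(as.vector(grad)[bnd_v], lab_v[bnd_v]) /
    pmax(1, sum_by(rep(1, sum(bnd_v)), lab_v[bnd_v]))
  int_v <- lab_v > 0 & !bnd_v
  n_int <- sum_by(rep(1, sum(int_v)), lab_v[int_v])
  mean_int <- ifelse(n_int > 0,
                     sum_by(num[int_v], lab_v[int_v]) / pmax(1, n_int),
                     sum_by(num[lab_v > 0], lab_v[lab_v > 0]) / area)
  margin <- ifelse(mean_int > 0, mean_bnd_grad / mean_int, 0)

  keep <- area >= config$min_area & area <= config$max_area &
    ar <= config$ar_max & circ >= config$circ_min & margin >= config$margin_min
  objects <- data.frame(
    label = seq_len(n), area = as.numeric(area), perimeter = as.numeric(per),
    centroid_row = as.numeric(fm[, "m.cx"]),
    centroid_col = as.numeric(fm[, "m.cy"]),
    aspect_ratio = as.numeric(ar), circularity = as.numeric(circ),
    margin_score = as.numeric(margin))[keep, , drop = FALSE]
  rownames(objects) <- NULL
  list(objects = objects, labels = lab, threshold = t_dapi,
       n_candidates = n)
}
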