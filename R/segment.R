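## Otsu threshold on an arbitrary-range matrix (EBImage's otsu expects a
## known range); returns -Inf for constant images.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(-Inf)
  xn <- (x - rng[1]) / diff(rng)
  t <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  rng[1] + t * diff(rng)
}

#' Segment nuclei from the DAPI channel
#'
#' Otsu threshold, hole filling, and a distance-transform watershed to
#' split touching nuclei; objects below `min_area` px are discarded.
#'
#' @param dapi 2-D DAPI intensity matrix (background-corrected).
#' @param min_area minimum nucleus area in px.
#' @param tolerance watershed tolerance (minimum object-height separation
#'   in distance-map units before two catchment basins are split).
#' @param smooth_sigma Gaussian pre-smoothing in px applied before
#'   thresholding, so chromatin texture does not fragment the nuclear
#'   mask; the raw channel is untouched (contrast QC reads it).
#' @return Integer label image; all zeros for a blank field.
#' @export
segment_nuclei <- function(dapi, min_area = 40, tolerance = 2,
                           smooth_sigma = 1) {
  stopifnot(is.matrix(dapi))
  if (smooth_sigma > 0)
    dapi <- as.matrix(EBImage::gblur(EBImage::Image(dapi),
                                     sigma = smooth_sigma))
  thr <- otsu_threshold(dapi)
  if (!is.finite(thr)) return(array(0L, dim = dim(dapi)))
  ## bimodality guard: on a blank (noise-only) field Otsu splits the noise
  ## itself; require the threshold to stand clear of the background class
  below <- dapi[dapi <= thr]
  if (length(below) > 1 &&
      (thr - mean(below)) < 3 * stats::sd(below))
    return(array(0L, dim = dim(dapi)))
  mask <- dapi > thr
  if (!any(mask) || mean(mask) > 0.5)
    return(array(0L, dim = dim(dapi)))
  mask <- EBImage::fillHull(EBImage::Image(mask))
  d <- EBImage::distmap(mask)
  labels <- EBImage::watershed(d, tolerance = tolerance, ext = 1)
  labels <- as.matrix(EBImage::imageData(labels))
  sizes <- table(labels[labels > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  labels[!labels %in% keep] <- 0L
  relabel(labels)
}

## relabel objects 1..n preserving order
relabel <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  out <- array(0L, dim = dim(labels))
  for (k in seq_along(ids)) out[labels == ids[k]] <- k
  out
}

#' Segment cells by seeded watershed on the inverted phalloidin channel
#'
#' The phalloidin channel is inverted so cells become bright basins with
#' low intensities along the cortical ridges, and flooded from the nucleus
#' seeds (EBImage's `propagate`, a seeded watershed on an
#' intensity-weighted geodesic metric). Foreground is estimated by Otsu
#' thresholding with a second pass when the first threshold isolates only
#' the bright cortical ridges; regions below the foreground threshold or
#' not reached from any seed form the excluded (cell-free) region.
#'
#' @param phalloidin 2-D phalloidin matrix (background-corrected).
#' @param nuclei nucleus label image from [segment_nuclei()] on the same
#'   field.
#' @param lambda `propagate` regularisation: small values let image
#'   gradients dominate the watershed metric.
#' @return List with `cell_labels` (integer label image; labels match the
#'   seeding nuclei) and `excluded_region_mask` (logical).
#' @export
segment_cells <- function(phalloidin, nuclei, lambda = 1e-4) {
  if (!all(dim(phalloidin) == dim(nuclei)))
    stop("phalloidin and nuclei dimensions differ")
  rng <- range(phalloidin)
  if (diff(rng) == 0) {
    fg <- matrix(TRUE, nrow(phalloidin), ncol(phalloidin))
  } else {
    t1 <- otsu_threshold(phalloidin)
    frac1 <- mean(phalloidin > t1)
    fg_thr <- t1
    if (frac1 < 0.3) {
      ## t1 likely separates ridges from everything else; re-threshold the
      ## sub-ridge intensities to recover the cell interiors
      below <- phalloidin[phalloidin <= t1]
      t2 <- otsu_threshold(matrix(below))
      if (is.finite(t2) && mean(phalloidin > t2) > frac1 + 0.1) fg_thr <- t2
    }
    fg <- phalloidin > fg_thr
  }
  if (max(nuclei) == 0)
    return(list(cell_labels = array(0L, dim = dim(phalloidin)),
                excluded_region_mask = !fg | TRUE))
  inv <- max(phalloidin) - phalloidin
  inv <- inv / max(inv, 1)
  labels <- EBImage::propagate(EBImage::Image(inv),
                               seeds = EBImage::Image(nuclei),
                               mask = EBImage::Image(fg), lambda = lambda)
  labels <- as.matrix(EBImage::imageData(labels))
  storage.mode(labels) <- "integer"
  list(cell_labels = labels, excluded_region_mask = !fg | labels == 0)
}
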