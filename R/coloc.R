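#' Percent integrated density of an ROI
#'
#' `%IntDens = (ROI IntDens / whole-cell ROI IntDens) x 100`, the measure
#' used to express the share of receptor signal inside an organelle ROI
#' relative to the whole cell.
#'
#' @param roi_int_dens integrated density (sum of pixel intensities) of
#'   the ROI.
#' @param whole_cell_int_dens integrated density of the whole-cell ROI
#'   (> 0); the ROI must be contained in it for the result to lie in
#'   [0, 100].
#' @return Percentage.
#' @examples
#' percent_intdens(50, 200) # 25
#' @export
percent_intdens <- function(roi_int_dens, whole_cell_int_dens) {
  if (any(whole_cell_int_dens == 0))
    stop("whole-cell integrated density is 0")
  stopifnot(all(roi_int_dens >= 0), all(whole_cell_int_dens > 0))
  100 * roi_int_dens / whole_cell_int_dens
}

#' Integrated density of a mask or polygon ROI
#'
#' @param channel 2-D intensity matrix.
#' @param roi logical mask of the same shape, or a two-column matrix of
#'   polygon vertices (x = col, y = row) which is rasterised by
#'   point-in-polygon.
#' @param pixel_size_um pixel size for the reported area.
#' @return List `int_dens`, `area_px`, `area_um2`.
#' @export
roi_intdens <- function(channel, roi, pixel_size_um = 1) {
  if (is.matrix(roi) && !is.logical(roi)) {
    stopifnot(ncol(roi) == 2)
    nr <- nrow(channel); nc <- ncol(channel)
    px <- expand.grid(y = seq_len(nr), x = seq_len(nc))
    inside <- point_in_polygon(px$x, px$y, roi[, 1], roi[, 2])
    roi <- matrix(inside, nr, nc)
  }
  stopifnot(is.logical(roi), all(dim(roi) == dim(channel)))
  if (!any(roi)) stop("empty ROI")
  list(int_dens = sum(channel[roi]), area_px = sum(roi),
       area_um2 = sum(roi) * pixel_size_um^2)
}

## even-odd ray-casting point-in-polygon (boundary-inclusive up to fp)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Colocalize two spot sets
#'
#' One-to-one greedy nearest-neighbour matching in increasing distance
#' order; a pair counts as colocalized when its distance is at most
#' `max_distance` px (2 px in the validation analyses). The colocalized
#' fraction is reported relative to channel A (and to B).
#'
#' @param spots_a,spots_b spot tables with `x`, `y` columns (same frame).
#' @param max_distance maximum pairing distance in px.
#' @return List (`coloc_result`): `n_spots_A`, `n_spots_B`,
#'   `n_colocalized`, `fraction_colocalized` (relative to A),
#'   `fraction_colocalized_B`, `max_distance_px`, `pairs`
#'   (`data.frame` of matched indices and distances).
#' @export
colocalize <- function(spots_a, spots_b, max_distance = 2.0) {
  na <- nrow(spots_a); nb <- nrow(spots_b)
  pairs <- data.frame(a = integer(0), b = integer(0), dist = numeric(0))
  if (na > 0 && nb > 0) {
    d <- sqrt(outer(spots_a$x, spots_b$x, "-")^2 +
              outer(spots_a$y, spots_b$y, "-")^2)
    idx <- which(d <= max_distance, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      ord <- order(d[idx])
      idx <- idx[ord, , drop = FALSE]
      used_a <- logical(na); used_b <- logical(nb)
      for (k in seq_len(nrow(idx))) {
        i <- idx[k, 1]; j <- idx[k, 2]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE; used_b[j] <- TRUE
          pairs <- rbind(pairs,
                         data.frame(a = i, b = j, dist = d[i, j]))
        }
      }
    }
  }
  n <- nrow(pairs)
  structure(list(n_spots_A = na, n_spots_B = nb, n_colocalized = n,
                 fraction_colocalized = if (na > 0) n / na else NA_real_,
                 fraction_colocalized_B = if (nb > 0) n / nb else NA_real_,
                 max_distance_px = max_distance, pairs = pairs),
            class = "coloc_result")
}

#' Summarize ROI measurements across replicates
#'
#' Mean and SD per condition with the acceptance rule that at least
#' `min_rois` ROIs from at least `min_images` images are analysed
#' (boundary inclusive).
#'
#' @param measurements `data.frame` with `condition`, `image`, `value`
#'   columns (one row per ROI).
#' @param min_rois,min_images validity minima.
#' @return `data.frame` per condition: `n_rois`, `n_images`, `mean`,
#'   `sd`, `valid`.
#' @export
summarize_replicates <- function(measurements, min_rois = 5,
                                 min_images = 5) {
  stopifnot(all(c("condition", "image", "value") %in%
                  names(measurements)))
  conds <- unique(measurements$condition)
  do.call(rbind, lapply(conds, function(cc) {
    s <- measurements[measurements$condition == cc, , drop = FALSE]
    data.frame(condition = cc, n_rois = nrow(s),
               n_images = length(unique(s$image)),
               mean = mean(s$value), sd = stats::sd(s$value),
               valid = nrow(s) >= min_rois &&
                 length(unique(s$image)) >= min_images)
  }))
}
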