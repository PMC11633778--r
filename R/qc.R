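## convex-hull area of a pixel set (shoelace over chull vertices, with a
## half-pixel inflation so single-row shapes do not degenerate to area 0)
chull_area <- function(px) {
  if (nrow(px) < 3) return(nrow(px))
  h <- grDevices::chull(px[, 1], px[, 2])
  v <- px[h, , drop = FALSE]
  n <- nrow(v)
  a <- abs(sum(v[, 1] * v[c(2:n, 1), 2] - v[c(2:n, 1), 1] * v[, 2])) / 2
  max(a, nrow(px))
}

#' Per-cell exclusion flags
#'
#' Flags the cells the screen excludes from analysis: cells touching the
#' field border, cells outside the plausible area range, cells with
#' saturated pixels in the analysed channels, and improperly segmented
#' cells (no seeding nucleus, or low solidity).
#'
#' @param cell_labels integer cell label image.
#' @param compartments output of [derive_compartments()] for the field.
#' @param channels named list of channel matrices (at least `DAPI` and
#'   `NOTCH1`).
#' @param bit_depth camera bit depth; saturation value is
#'   `2^bit_depth - 1`.
#' @param min_area,max_area cell area bounds in px^2.
#' @param sat_frac maximum tolerated fraction of saturated pixels per cell.
#' @param min_solidity minimum area / convex-hull-area ratio.
#' @param sat_channels channels checked for saturation.
#' @return `data.frame` with one row per cell: `cell`, the individual
#'   flags, and `passed` (no flag set).
#' @export
qc_cells <- function(cell_labels, compartments, channels, bit_depth = 16,
                     min_area = 200, max_area = 20000, sat_frac = 0.005,
                     min_solidity = 0.8,
                     sat_channels = c("DAPI", "NOTCH1")) {
  cell_idx <- label_index(cell_labels)
  ids <- as.integer(names(cell_idx))
  nuc_ids <- setdiff(unique(as.vector(compartments$nucleus)), 0)
  sat_val <- 2^bit_depth - 1
  nr <- nrow(cell_labels); nc <- ncol(cell_labels)
  res <- lapply(ids, function(cid) {
    lin <- cell_idx[[as.character(cid)]]
    px <- cbind(((lin - 1L) %% nr) + 1L, ((lin - 1L) %/% nr) + 1L)
    area <- nrow(px)
    border <- any(px[, 1] == 1 | px[, 1] == nr |
                  px[, 2] == 1 | px[, 2] == nc)
    sat <- any(vapply(sat_channels, function(ch) {
      v <- channels[[ch]][lin]
      mean(v >= sat_val) > sat_frac
    }, logical(1)))
    has_nuc <- cid %in% nuc_ids
    solidity <- area / chull_area(px)
    malformed <- !has_nuc || solidity < min_solidity
    data.frame(cell = cid, border = border, too_small = area < min_area,
               too_big = area > max_area, saturated = sat,
               malformed = malformed, area = area)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(cell = integer(0), border = logical(0),
               too_small = logical(0), too_big = logical(0),
               saturated = logical(0), malformed = logical(0),
               area = integer(0))
  out$passed <- !(out$border | out$too_small | out$too_big |
                  out$saturated | out$malformed)
  out
}

#' Nuclear intensity contrast
#'
#' Coefficient of variation of DAPI intensities over the nucleus dilated by
#' `dilate_radius` px; the dilation takes in the steep nuclear edge, which
#' defocus blur flattens, so contrast decreases monotonically with blur and
#' is invariant to intensity scaling.
#'
#' @param dapi 2-D DAPI matrix.
#' @param nucleus_mask logical matrix, one nucleus.
#' @param dilate_radius dilation radius in px.
#' @return Contrast value (SD / mean over the dilated region).
#' @export
nucleus_contrast <- function(dapi, nucleus_mask, dilate_radius = 2) {
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  region <- as.matrix(EBImage::dilate(
    EBImage::Image(nucleus_mask),
    EBImage::makeBrush(2 * dilate_radius + 1, "disc"))) > 0
  v <- dapi[region]
  m <- mean(v)
  if (m == 0) return(0)
  stats::sd(v) / m
}

## contrasts for every nucleus of a label image; one grayscale dilation of
## the whole label image (valid because segmented nuclei are farther apart
## than 2 * dilate_radius)
nuclei_contrasts <- function(dapi, nucleus_labels, dilate_radius = 2) {
  ids <- setdiff(sort(unique(as.vector(nucleus_labels))), 0)
  if (!length(ids)) return(numeric(0))
  dil <- as.matrix(EBImage::dilate(
    EBImage::Image(nucleus_labels),
    EBImage::makeBrush(2 * dilate_radius + 1, "disc")))
  v <- split(dapi[dil > 0], as.vector(dil[dil > 0]))
  out <- vapply(as.character(ids), function(k) {
    x <- v[[k]]
    if (is.null(x) || !length(x)) return(0)
    m <- mean(x)
    if (m == 0) 0 else stats::sd(x) / m
  }, numeric(1))
  unname(out)
}

#' Tukey lower inner fence of a sample
#'
#' `LIF = Q1 - k * (Q3 - Q1)` with quantiles by linear interpolation
#' (type 7). With the default `k = 1.5` this is the standard boxplot lower
#' fence, below which roughly the extreme ~0.3% of a normal sample falls.
#'
#' @param values numeric vector, length >= 4.
#' @param k fence multiplier.
#' @return Named numeric vector `c(Q1, Q3, LIF)`.
#' @examples
#' lower_inner_fence(1:100)
#' @export
lower_inner_fence <- function(values, k = 1.5) {
  if (length(values) < 4) stop("need >= 4 values for fence estimation")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  c(Q1 = q[1], Q3 = q[2], LIF = q[1] - k * (q[2] - q[1]))
}

#' Classify a well's fields as in or out of focus
#'
#' The fence is computed over the nuclear contrast values of *all* nuclei
#' detected in the well; a field is called out of focus when strictly more
#' than `min_frac` of its nuclei fall below the lower inner fence. Fields
#' with no detected nuclei are counted as out of focus (they contribute no
#' analysable cells).
#'
#' @param contrasts `data.frame` with columns `field` and `contrast`, one
#'   row per nucleus in the well.
#' @param fields optional vector of all field ids imaged for the well
#'   (so that nucleus-free fields are still classified).
#' @param min_frac fraction threshold (strict inequality).
#' @param k fence multiplier, see [lower_inner_fence()].
#' @return List with `Q1`, `Q3`, `LIF` and `fields`, a `data.frame`
#'   (`field`, `n_nuclei`, `frac_below_LIF`, `out_of_focus`).
#' @export
classify_fields_focus <- function(contrasts, fields = NULL, min_frac = 0.5,
                                  k = 1.5) {
  stopifnot(is.data.frame(contrasts),
            all(c("field", "contrast") %in% names(contrasts)))
  if (is.null(fields)) fields <- sort(unique(contrasts$field))
  fence <- lower_inner_fence(contrasts$contrast, k = k)
  per <- do.call(rbind, lapply(fields, function(f) {
    v <- contrasts$contrast[contrasts$field == f]
    n <- length(v)
    frac <- if (n == 0) NA_real_ else mean(v < fence[["LIF"]])
    data.frame(field = f, n_nuclei = n, frac_below_LIF = frac,
               out_of_focus = n == 0 || frac > min_frac)
  }))
  list(Q1 = fence[["Q1"]], Q3 = fence[["Q3"]], LIF = fence[["LIF"]],
       fields = per)
}
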