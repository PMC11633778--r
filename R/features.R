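#' Per-cell NOTCH1 compartment features
#'
#' Mean (and total) NOTCH1 intensity per compartment for every segmented
#' cell, plus the cytosolic punctum count. An empty compartment records
#' intensity 0 with a warning.
#'
#' @param cell_labels integer cell label image.
#' @param compartments output of [derive_compartments()].
#' @param notch 2-D NOTCH1 matrix.
#' @param spots spot table from [detect_spots()] (columns `x`, `y`); spots
#'   are assigned to the cell whose cytosol they fall in.
#' @param spot_min minimum puncta for `has_spots`.
#' @return `data.frame`: `cell`, `nuc_intensity`, `memb_intensity`,
#'   `cyto_intensity`, `cell_intensity` (means), matching `*_total` sums,
#'   `n_spots`, `has_spots`.
#' @export
measure_cells <- function(cell_labels, compartments, notch,
                          spots = NULL, spot_min = 2) {
  ids <- setdiff(sort(unique(as.vector(cell_labels))), 0)
  spot_cell <- integer(0)
  if (!is.null(spots) && nrow(spots) > 0) {
    pos <- cbind(round(spots$y), round(spots$x))
    spot_cell <- compartments$cytosol[pos]
  }
  nuc_idx <- label_index(compartments$nucleus)
  ring_idx <- label_index(compartments$ring)
  cyto_idx <- label_index(compartments$cytosol)
  cell_idx <- label_index(cell_labels)
  res <- lapply(ids, function(cid) {
    key <- as.character(cid)
    comp_v <- list(nuc = notch[nuc_idx[[key]]],
                   memb = notch[ring_idx[[key]]],
                   cyto = notch[cyto_idx[[key]]],
                   cell = notch[cell_idx[[key]]])
    empty <- names(comp_v)[vapply(comp_v, length, integer(1)) == 0]
    if (length(empty))
      warning("cell ", cid, ": empty compartment(s) ",
              paste(empty, collapse = ", "), "; intensity recorded as 0")
    mn <- vapply(comp_v, function(v) if (length(v)) mean(v) else 0,
                 numeric(1))
    tot <- vapply(comp_v, sum, numeric(1))
    n_sp <- sum(spot_cell == cid)
    data.frame(cell = cid,
               nuc_intensity = mn[["nuc"]], memb_intensity = mn[["memb"]],
               cyto_intensity = mn[["cyto"]], cell_intensity = mn[["cell"]],
               nuc_total = tot[["nuc"]], memb_total = tot[["memb"]],
               cyto_total = tot[["cyto"]], cell_total = tot[["cell"]],
               n_spots = n_sp, has_spots = n_sp >= spot_min)
  })
  if (length(res)) do.call(rbind, res) else
    data.frame(cell = integer(0), nuc_intensity = numeric(0),
               memb_intensity = numeric(0), cyto_intensity = numeric(0),
               cell_intensity = numeric(0), nuc_total = numeric(0),
               memb_total = numeric(0), cyto_total = numeric(0),
               cell_total = numeric(0), n_spots = integer(0),
               has_spots = logical(0))
}

#' Aggregate per-cell features to the per-well screen parameters
#'
#' Produces the named parameters used for hit calling:
#' `QC1_NoOfAnalysedCells` (cell count, the viability readout),
#' `N1_NucNotch`, `N3_MembNotch`, `N4_CellNotch` (mean compartment
#' intensities over analysed cells), `N5_PercentOfCellsWithSpots` and
#' `N9_NoOfSpotsPerCell`. Intensity and spot parameters are `NA` when
#' fewer than `min_cells` cells were analysed.
#'
#' @param cells per-cell feature `data.frame` from [measure_cells()],
#'   already restricted to QC-passed cells from in-focus fields.
#' @param min_cells minimum analysed cells for the intensity parameters to
#'   be considered defined.
#' @return One-row `data.frame` of well parameters.
#' @export
aggregate_well <- function(cells, min_cells = 50) {
  n <- nrow(cells)
  if (n == 0)
    return(data.frame(QC1_NoOfAnalysedCells = 0L, N1_NucNotch = NA_real_,
                      N3_MembNotch = NA_real_, N4_CellNotch = NA_real_,
                      N5_PercentOfCellsWithSpots = NA_real_,
                      N9_NoOfSpotsPerCell = NA_real_))
  out <- data.frame(
    QC1_NoOfAnalysedCells = n,
    N1_NucNotch = mean(cells$nuc_intensity),
    N3_MembNotch = mean(cells$memb_intensity),
    N4_CellNotch = mean(cells$cell_intensity),
    N5_PercentOfCellsWithSpots = 100 * mean(cells$has_spots),
    N9_NoOfSpotsPerCell = mean(cells$n_spots))
  if (n < min_cells)
    out[, -1] <- NA_real_
  out
}
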