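#' Analyse one field image
#'
#' Runs the per-field stages in order: background correction, nucleus
#' segmentation from DAPI, seeded-watershed cell segmentation from
#' inverted phalloidin, compartment derivation, cell exclusion flags,
#' per-nucleus contrast (for the well-level focus QC), puncta detection in
#' the cytosol, and per-cell feature measurement.
#'
#' @param field a field object (list with `channels`; e.g. from
#'   [render_field()]).
#' @param cfg a [screen_config()].
#' @return List: `cells` (per-cell features joined with QC flags),
#'   `contrasts` (per-nucleus contrast values), `n_nuclei`,
#'   `nucleus_labels`, `cell_labels`, `excluded_region_mask`, `spots`.
#' @export
analyze_field <- function(field, cfg = screen_config()) {
  stopifnot(!is.null(field$channels))
  corr <- correct_background(field, radius = cfg$bg_radius)
  dapi <- corr$channels$DAPI
  phal <- corr$channels$phalloidin
  notch <- corr$channels$NOTCH1

  nuclei <- segment_nuclei(dapi, min_area = cfg$min_nucleus_area)
  seg <- segment_cells(phal, nuclei)
  comp <- derive_compartments(seg$cell_labels, nuclei,
                              ring_width_px = cfg$ring_width_px)
  qc <- qc_cells(seg$cell_labels, comp, field$channels,
                 bit_depth = if (is.null(field$bit_depth)) 16
                             else field$bit_depth,
                 min_area = cfg$min_area, max_area = cfg$max_area,
                 sat_frac = cfg$sat_frac, min_solidity = cfg$min_solidity)
  contrasts <- if (max(nuclei) > 0)
    nuclei_contrasts(dapi, nuclei) else numeric(0)
  spots <- detect_spots(notch, region_mask = comp$cytosol > 0,
                        snr_threshold = cfg$snr_threshold,
                        spot_sigma_px = cfg$spot_sigma_px)
  cells <- measure_cells(seg$cell_labels, comp, notch, spots,
                         spot_min = cfg$spot_min)
  cells <- merge(cells, qc, by = "cell")
  list(cells = cells, contrasts = contrasts, n_nuclei = max(nuclei),
       nucleus_labels = nuclei, cell_labels = seg$cell_labels,
       excluded_region_mask = seg$excluded_region_mask, spots = spots)
}

#' Analyse all fields of one well
#'
#' Per-field analysis, then well-level focus QC over the pooled nuclear
#' contrasts; cells from out-of-focus fields and QC-flagged cells are
#' dropped before aggregation to the well parameters.
#'
#' @param fields list of field objects belonging to one well.
#' @param cfg a [screen_config()].
#' @return List: `features` (one-row well parameter `data.frame`),
#'   `focus` (the focus QC result), `cells` (per-cell table with `field`
#'   column), `n_fields_used`.
#' @export
analyze_well <- function(fields, cfg = screen_config()) {
  res <- lapply(fields, analyze_field, cfg = cfg)
  contrasts <- do.call(rbind, lapply(seq_along(res), function(i) {
    v <- res[[i]]$contrasts
    if (length(v)) data.frame(field = i, contrast = v) else NULL
  }))
  focus <- if (!is.null(contrasts) && nrow(contrasts) >= 4) {
    classify_fields_focus(contrasts, fields = seq_along(res),
                          min_frac = cfg$focus_min_frac, k = cfg$fence_k)
  } else {
    list(Q1 = NA, Q3 = NA, LIF = NA,
         fields = data.frame(field = seq_along(res),
                             n_nuclei = vapply(res, `[[`, 0, "n_nuclei"),
                             frac_below_LIF = NA_real_,
                             out_of_focus = TRUE))
  }
  in_focus <- focus$fields$field[!focus$fields$out_of_focus]
  cells <- do.call(rbind, lapply(in_focus, function(i) {
    cc <- res[[i]]$cells
    if (nrow(cc)) cbind(field = i, cc) else NULL
  }))
  passed <- if (is.null(cells)) data.frame() else
    cells[cells$passed, , drop = FALSE]
  list(features = aggregate_well(passed, min_cells = cfg$min_cells),
       focus = focus, cells = cells,
       n_fields_used = length(in_focus))
}

#' Analyse a simulated (or loaded) screen
#'
#' Groups fields by well, runs [analyze_well()], and joins the well
#' parameters with the plate layout annotation.
#'
#' @param fields named list of field objects carrying `well` elements
#'   (e.g. from [simulate_screen()]).
#' @param layout plate layout.
#' @param cfg a [screen_config()].
#' @return `data.frame`: one row per analysed well with layout columns and
#'   the six well parameters, plus attribute `"focus"` (per-well focus QC
#'   tables).
#' @export
analyze_screen <- function(fields, layout, cfg = screen_config()) {
  wells <- unique(vapply(fields, `[[`, "", "well"))
  focus_tabs <- list()
  rows <- lapply(wells, function(w) {
    fw <- fields[vapply(fields, function(f) identical(f$well, w),
                        logical(1))]
    res <- analyze_well(fw, cfg = cfg)
    focus_tabs[[w]] <<- res$focus$fields
    lay <- layout[match(w, layout$well), , drop = FALSE]
    cbind(lay[, c("barcode", "well", "condition", "gene", "role",
                  "replicate")],
          res$features, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "focus") <- focus_tabs
  out
}
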