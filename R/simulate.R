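role_phenotype <- function(role, gene, phenotype_map, default_phenotype,
                           presets = phenotype_presets()) {
  switch(role,
    NT = presets$NT,
    no_siRNA = presets$NT,
    pos_ctrl_PSENEN = presets$signaling_off,
    transfection_ctrl_PLK1 = presets$toxic,
    sample = {
      ph <- phenotype_map[[gene]]
      if (is.null(ph)) ph <- default_phenotype
      if (is.null(ph))
        stop("no phenotype for gene ", gene, " and no default given")
      ph
    },
    NULL)
}

#' Simulate image fields for a screening plate
#'
#' Renders `fields_per_well` fields for every cell-bearing well of a plate
#' layout. Per-well expected cell counts are scaled by the phenotype's
#' `cell_count_mult`; a configurable fraction of each well's fields is
#' rendered out of focus (Gaussian defocus of `oof_sigma`). All randomness
#' flows from one seeded generator, so a given seed reproduces the images
#' byte for byte.
#'
#' @param layout plate layout from [make_plate_layout()]; media and empty
#'   wells are skipped.
#' @param phenotype_map named list gene -> [phenotype_spec()]; genes absent
#'   from the map get `default_phenotype`. Control wells use the built-in
#'   presets for their role.
#' @param default_phenotype phenotype for unmapped sample genes (default
#'   NT-like); set to `NULL` to require an explicit phenotype per gene.
#' @param fields_per_well fields imaged per well (the screen used 8).
#' @param mean_cells_per_field Poisson mean of cells per field before the
#'   viability multiplier.
#' @param oof_frac fraction of fields per well rendered out of focus
#'   (rounded to a whole number of fields).
#' @param oof_sigma defocus blur sigma in px for out-of-focus fields.
#' @param img_size field size in px, c(rows, cols).
#' @param noise camera noise parameters, see [render_field()].
#' @param seed integer seed.
#' @return Named list of `synthetic_field` objects keyed `"<well>_f<k>"`,
#'   each carrying `well`, `field`, `barcode` and `condition` elements.
#' @export
simulate_screen <- function(layout, phenotype_map = list(),
                            default_phenotype = phenotype_presets()$NT,
                            fields_per_well = 8, mean_cells_per_field = 25,
                            oof_frac = 0, oof_sigma = 4,
                            img_size = c(256, 256),
                            noise = list(gain = 1, read_sd = 10),
                            seed = 1L) {
  stopifnot(fields_per_well >= 1, oof_frac >= 0, oof_frac <= 1)
  wells <- layout[!layout$role %in% c("media", "empty"), , drop = FALSE]
  presets <- phenotype_presets()
  local_seed(seed, {
    out <- list()
    n_oof <- round(oof_frac * fields_per_well)
    for (i in seq_len(nrow(wells))) {
      w <- wells[i, ]
      ph <- role_phenotype(w$role, w$gene, phenotype_map, default_phenotype,
                          presets)
      oof_fields <- if (n_oof > 0)
        sample.int(fields_per_well, n_oof) else integer(0)
      ## one density per well: fields of a confluent well sample the same
      ## monolayer, so cell counts vary between wells, not within them
      n_cells <- stats::rpois(1, mean_cells_per_field * ph$cell_count_mult)
      for (f in seq_len(fields_per_well)) {
        fld <- render_field(ph, n_cells, img_size = img_size, noise = noise,
                            blur_sigma = if (f %in% oof_fields) oof_sigma
                                         else 0,
                            seed = NULL)
        fld$well <- w$well; fld$field <- f
        fld$barcode <- w$barcode; fld$condition <- w$condition
        out[[paste0(w$well, "_f", f)]] <- fld
      }
    }
    out
  })
}

#' Simulate a reporter (luciferase + resazurin) plate readout
#'
#' Luminescence is proportional to the phenotype's signaling multiplier
#' times its viability multiplier (times a stimulation factor on EGTA
#' plates); resazurin viability fluorescence is proportional to the
#' viability multiplier alone. Both carry multiplicative log-normal noise
#' with coefficient of variation `cv` (mean exactly 1, so `cv = 0` gives
#' noiseless readouts). Media and empty wells read instrument background.
#'
#' @param layout plate layout.
#' @param phenotype_map named list gene -> [phenotype_spec()].
#' @param default_phenotype phenotype for unmapped sample genes.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param base_lum,base_viab baseline NT readouts in instrument units.
#' @param stim_factor fold induction of baseline signaling on EGTA plates.
#' @param background instrument background for cell-free wells.
#' @param seed integer seed.
#' @return `data.frame` with `well`, `role`, `gene`, `condition`,
#'   `barcode`, `replicate`, `luminescence`, `viability`.
#' @export
simulate_reporter_plate <- function(layout, phenotype_map = list(),
                                    default_phenotype =
                                      phenotype_presets()$NT,
                                    cv = 0.1, base_lum = 1000,
                                    base_viab = 1000, stim_factor = 5,
                                    background = 5, seed = 1L) {
  stopifnot(cv >= 0)
  presets <- phenotype_presets()
  n <- nrow(layout)
  sig <- ccm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ph <- role_phenotype(layout$role[i], layout$gene[i], phenotype_map,
                         default_phenotype, presets)
    if (!is.null(ph)) {
      sig[i] <- ph$signaling_mult
      ccm[i] <- ph$cell_count_mult
    }
  }
  local_seed(seed, {
    stim <- ifelse(layout$condition == "EGTA", stim_factor, 1)
    nl <- if (cv > 0)
      matrix(stats::rlnorm(2 * n, -cv^2 / 2, cv), n, 2) else
      matrix(1, n, 2)
    lum <- ifelse(is.na(sig), background,
                  base_lum * sig * ccm * stim * nl[, 1])
    viab <- ifelse(is.na(ccm), background, base_viab * ccm * nl[, 2])
    data.frame(well = layout$well, role = layout$role, gene = layout$gene,
               condition = layout$condition, barcode = layout$barcode,
               replicate = layout$replicate,
               luminescence = lum, viability = viab,
               stringsAsFactors = FALSE)
  })
}

#' Simulate per-well phenotype features directly (statistical twin)
#'
#' Generates the per-well parameter table that the imaging pipeline would
#' produce, without rendering images: expected feature values are derived
#' from each well's phenotype and Gaussian well-to-well noise is added.
#' This is the fast generator used for hit-calling power studies at full
#' plate scale; the image-based path ([simulate_screen()] +
#' [analyze_screen()]) validates the same feature definitions at small
#' scale.
#'
#' Expected values: `N3_MembNotch` and `N1_NucNotch` scale linearly with the
#' membrane and nuclear signal fractions, `N4_CellNotch` is constant (total
#' NOTCH1 per cell is phenotype-invariant), `N9_NoOfSpotsPerCell` equals
#' the phenotype spot rate, and `N5_PercentOfCellsWithSpots` is the Poisson
#' probability of a cell carrying at least `spot_min` puncta.
#'
#' @param layout plate layout.
#' @param phenotype_map named list gene -> [phenotype_spec()].
#' @param default_phenotype phenotype for unmapped sample genes.
#' @param n_cells_mean expected analysed cells per NT well.
#' @param noise_sd named numeric vector of additive well-to-well SDs for
#'   `QC1`, `N1`, `N3`, `N4`, `N5`, `N9`.
#' @param spot_min minimum puncta for a cell to count as "with spots".
#' @param seed integer seed.
#' @return `data.frame` with layout annotation plus the six well parameters.
#' @export
simulate_well_features <- function(layout, phenotype_map = list(),
                                   default_phenotype =
                                     phenotype_presets()$NT,
                                   n_cells_mean = 350,
                                   noise_sd = c(QC1 = 30, N1 = 8, N3 = 30,
                                                N4 = 10, N5 = 4, N9 = 0.25),
                                   spot_min = 2, seed = 1L) {
  presets <- phenotype_presets()
  wells <- layout[!layout$role %in% c("media", "empty"), , drop = FALSE]
  local_seed(seed, {
    n <- nrow(wells)
    exp_tab <- t(vapply(seq_len(n), function(i) {
      w <- wells[i, ]
      ph <- role_phenotype(w$role, w$gene, phenotype_map, default_phenotype,
                          presets)
      c(QC1 = n_cells_mean * ph$cell_count_mult,
        N1 = 1000 * ph$nuc_frac,
        N3 = 1000 * ph$pm_frac,
        N4 = 100,
        N5 = 100 * (1 - stats::ppois(spot_min - 1, ph$spot_rate)),
        N9 = ph$spot_rate)
    }, numeric(6)))
    obs <- exp_tab + vapply(c("QC1", "N1", "N3", "N4", "N5", "N9"),
                            function(p) stats::rnorm(n, 0, noise_sd[[p]]),
                            numeric(n))
    data.frame(barcode = wells$barcode, well = wells$well,
               condition = wells$condition, gene = wells$gene,
               role = wells$role, replicate = wells$replicate,
               QC1_NoOfAnalysedCells = pmax(0, round(obs[, "QC1"])),
               N1_NucNotch = pmax(0, obs[, "N1"]),
               N3_MembNotch = pmax(0, obs[, "N3"]),
               N4_CellNotch = pmax(0, obs[, "N4"]),
               N5_PercentOfCellsWithSpots = pmin(100, pmax(0, obs[, "N5"])),
               N9_NoOfSpotsPerCell = pmax(0, obs[, "N9"]),
               stringsAsFactors = FALSE)
  })
}
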