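one_cell_setup <- function(value = 500) {
  cl <- array(0L, c(64, 64)); cl[10:50, 10:50] <- 1L
  nl <- array(0L, c(64, 64)); nl[25:35, 25:35] <- 1L
  comp <- derive_compartments(cl, nl, ring_width_px = 3)
  notch <- matrix(value, 64, 64)
  list(cl = cl, comp = comp, notch = notch)
}

test_that("uniform intensity gives equal compartment means", {
  s <- one_cell_setup(500)
  cf <- measure_cells(s$cl, s$comp, s$notch)
  expect_equal(cf$nuc_intensity, 500)
  expect_equal(cf$memb_intensity, 500)
  expect_equal(cf$cyto_intensity, 500)
  expect_equal(cf$cell_intensity, 500)
})

test_that("area-weighted compartment means reproduce the cell mean", {
  f <- render_field(phenotype_presets()$spots, 8, img_size = c(160, 160),
                    seed = 71)
  comp <- derive_compartments(f$truth$cell_labels, f$truth$nucleus_labels, 3)
  cf <- measure_cells(f$truth$cell_labels, comp, f$channels$NOTCH1)
  for (i in seq_len(nrow(cf))) {
    an <- sum(comp$nucleus == cf$cell[i])
    ar <- sum(comp$ring == cf$cell[i])
    ac <- sum(comp$cytosol == cf$cell[i])
    wmean <- (an * cf$nuc_intensity[i] + ar * cf$memb_intensity[i] +
                ac * cf$cyto_intensity[i]) / (an + ar + ac)
    expect_equal(wmean, cf$cell_intensity[i], tolerance = 1e-6)
  }
})

test_that("a pure-membrane phenotype shows ring-dominated intensities", {
  ph <- phenotype_spec(1, 0, 0)
  f <- render_field(ph, 8, img_size = c(160, 160), seed = 72)
  comp <- derive_compartments(f$truth$cell_labels, f$truth$nucleus_labels, 3)
  cf <- measure_cells(f$truth$cell_labels, comp, f$channels$NOTCH1)
  expect_true(all(cf$memb_intensity > 3 * cf$cyto_intensity))
})

test_that("empty compartments are recorded as zero with a warning", {
  cl <- array(0L, c(32, 32)); cl[10:20, 10:20] <- 1L
  nl <- array(0L, c(32, 32))  # no nucleus
  comp <- derive_compartments(cl, nl, ring_width_px = 0)
  expect_warning(cf <- measure_cells(cl, comp, matrix(100, 32, 32)),
                 "empty compartment")
  expect_equal(cf$nuc_intensity, 0)
  expect_equal(cf$memb_intensity, 0)
  expect_equal(cf$cyto_intensity, 100)
})

test_that("spot counts respect the has_spots threshold", {
  f <- render_field(phenotype_presets()$spots, 10, img_size = c(192, 192),
                    seed = 73)
  a <- analyze_field(f, screen_config())
  expect_true(all(a$cells$has_spots == (a$cells$n_spots >= 2)))
})

test_that("well aggregation matches brute-force arithmetic", {
  cells <- data.frame(
    cell = 1:3,
    nuc_intensity = c(10, 20, 30), memb_intensity = c(5, 15, 25),
    cyto_intensity = c(1, 2, 3), cell_intensity = c(4, 8, 12),
    n_spots = c(0, 2, 4), has_spots = c(FALSE, TRUE, TRUE))
  wf <- aggregate_well(cells, min_cells = 1)
  expect_equal(wf$QC1_NoOfAnalysedCells, 3)
  expect_equal(wf$N1_NucNotch, (10 + 20 + 30) / 3)
  expect_equal(wf$N3_MembNotch, (5 + 15 + 25) / 3)
  expect_equal(wf$N4_CellNotch, (4 + 8 + 12) / 3)
  expect_equal(wf$N5_PercentOfCellsWithSpots, 100 * 2 / 3)
  expect_equal(wf$N9_NoOfSpotsPerCell, 2)
})

test_that("degenerate wells yield QC1 = 0 or undefined parameters", {
  wf0 <- aggregate_well(data.frame())
  expect_equal(wf0$QC1_NoOfAnalysedCells, 0)
  expect_true(is.na(wf0$N1_NucNotch))
  cells <- data.frame(cell = 1:10, nuc_intensity = 1, memb_intensity = 1,
                      cyto_intensity = 1, cell_intensity = 1,
                      n_spots = c(rep(2, 4), rep(0, 6)),
                      has_spots = c(rep(TRUE, 4), rep(FALSE, 6)))
  wf <- aggregate_well(cells, min_cells = 1)
  expect_equal(wf$N5_PercentOfCellsWithSpots, 40)
  # below min_cells the intensity parameters are undefined
  wf2 <- aggregate_well(cells, min_cells = 50)
  expect_equal(wf2$QC1_NoOfAnalysedCells, 10)
  expect_true(is.na(wf2$N5_PercentOfCellsWithSpots))
})
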