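# draw a filled disc into a matrix
draw_disc <- function(img, r0, c0, radius, value) {
  rr <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cc <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  img[(rr - r0)^2 + (cc - c0)^2 <= radius^2] <- value
  img
}

test_that("a blank field yields zero nuclei", {
  blank <- matrix(50, 128, 128)
  expect_equal(max(segment_nuclei(blank)), 0)
  noisy <- blank + matrix(rnorm(128^2, 0, 10), 128)
  expect_equal(max(segment_nuclei(noisy)), 0)
})

test_that("non-touching nuclei are recovered with accurate centroids", {
  f <- render_field(phenotype_presets()$NT, 12, img_size = c(192, 192),
                    seed = 21)
  found <- segment_nuclei(correct_background(f$channels$DAPI))
  expect_equal(max(found), max(f$truth$nucleus_labels))
  tc <- label_centroids(f$truth$nucleus_labels)
  fc <- label_centroids(found)
  # pair centroids by nearest neighbour
  for (i in seq_len(nrow(tc))) {
    d <- sqrt((fc$row - tc$row[i])^2 + (fc$col - tc$col[i])^2)
    expect_lt(min(d), 2)
  }
})

test_that("two nuclei separated by a small gap stay distinct", {
  img <- matrix(50, 96, 96)
  img <- draw_disc(img, 48, 40, 7, 2500)
  img <- draw_disc(img, 48, 57, 7, 2500)  # 3-px gap between rims
  labs <- segment_nuclei(img)
  expect_equal(max(labs), 2)
})

test_that("uniform phalloidin with one nucleus gives one full-frame cell", {
  phal <- matrix(500, 96, 96)
  nuc <- array(0L, dim = c(96, 96))
  nuc[40:56, 40:56] <- 1L
  seg <- segment_cells(phal, nuc)
  expect_equal(sort(unique(as.vector(seg$cell_labels))), 1)
  expect_false(any(seg$excluded_region_mask))
})

test_that("shape mismatch between channels is an error", {
  expect_error(segment_cells(matrix(0, 10, 10), array(0L, c(8, 8))),
               "differ")
})

test_that("cell boundaries follow the phalloidin ridges", {
  f <- render_field(phenotype_presets()$NT, 2, img_size = c(128, 128),
                    seed = 31)
  a <- analyze_field(f, screen_config())
  expect_equal(max(a$cell_labels), 2)
  # distance from each recovered boundary pixel to the truth boundary
  expect_lt(boundary_distance(a$cell_labels, f$truth$cell_labels), 2)
})

test_that("cell-free regions land in the excluded mask", {
  f <- render_field(phenotype_presets()$NT, 3, img_size = c(256, 256),
                    seed = 32)
  a <- analyze_field(f, screen_config())
  truth_bg <- f$truth$cell_labels == 0
  expect_gte(sum(a$excluded_region_mask & truth_bg) / sum(truth_bg), 0.95)
})

test_that("compartments partition each cell exactly", {
  f <- render_field(phenotype_presets()$NT, 8, img_size = c(160, 160),
                    seed = 33)
  cl <- f$truth$cell_labels
  comp <- derive_compartments(cl, f$truth$nucleus_labels, ring_width_px = 3)
  for (cid in seq_len(max(cl))) {
    cell_px <- sum(cl == cid)
    n <- sum(comp$nucleus == cid)
    r <- sum(comp$ring == cid)
    cy <- sum(comp$cytosol == cid)
    expect_equal(n + r + cy, cell_px)
    # pairwise disjoint by construction of label images
    expect_equal(sum((comp$nucleus == cid) & (comp$ring == cid)), 0)
  }
})

test_that("ring width zero reduces the partition to cell minus nucleus", {
  f <- render_field(phenotype_presets()$NT, 5, img_size = c(128, 128),
                    seed = 34)
  comp <- derive_compartments(f$truth$cell_labels, f$truth$nucleus_labels,
                              ring_width_px = 0)
  expect_equal(sum(comp$ring > 0), 0)
  expect_equal(sum(comp$cytosol > 0),
               sum(f$truth$cell_labels > 0) - sum(comp$nucleus > 0))
})

test_that("orphan nuclei are dropped with a warning", {
  cl <- array(0L, c(64, 64)); cl[10:30, 10:30] <- 1L
  nl <- array(0L, c(64, 64)); nl[15:20, 15:20] <- 1L; nl[45:50, 45:50] <- 2L
  expect_warning(comp <- derive_compartments(cl, nl), "outside all cells")
  expect_equal(comp$cells$nucleus, 1L)
})

test_that("QC flags catch border, saturated and malformed cells", {
  f <- render_field(phenotype_presets()$NT, 15, img_size = c(192, 192),
                    seed = 35)
  cl <- f$truth$cell_labels
  comp <- derive_compartments(cl, f$truth$nucleus_labels, 3)
  # plant a saturated interior cell
  interior <- vapply(seq_len(max(cl)), function(cid) {
    px <- which(cl == cid, arr.ind = TRUE)
    !any(px[, 1] == 1 | px[, 1] == nrow(cl) |
           px[, 2] == 1 | px[, 2] == ncol(cl))
  }, logical(1))
  target <- which(interior)[1]
  f$channels$NOTCH1[cl == target] <- 65535
  qc <- qc_cells(cl, comp, f$channels, min_area = 50)
  expect_true(qc$saturated[qc$cell == target])
  expect_equal(sum(qc$saturated), 1)
  # border flags match the geometry
  expect_equal(qc$border, !interior)
  # a cell without a nucleus is malformed
  comp2 <- comp
  comp2$nucleus[comp2$nucleus == target] <- 0L
  qc2 <- qc_cells(cl, comp2, f$channels, min_area = 50)
  expect_true(qc2$malformed[qc2$cell == target])
  expect_true(all(qc$passed == !(qc$border | qc$too_small | qc$too_big |
                                   qc$saturated | qc$malformed)))
})
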