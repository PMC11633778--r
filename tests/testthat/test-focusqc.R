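test_that("the fence matches an independent quantile oracle", {
  x <- as.numeric(1:100)
  f <- lower_inner_fence(x)
  expect_equal(f[["LIF"]], oracle_lif(x), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:100) {
    v <- rnorm(sample(4:60, 1))
    f <- lower_inner_fence(v)
    expect_equal(f[["Q1"]], oracle_quantile7(v, 0.25), tolerance = 1e-9)
    expect_equal(f[["Q3"]], oracle_quantile7(v, 0.75), tolerance = 1e-9)
    expect_equal(f[["LIF"]], oracle_lif(v), tolerance = 1e-9)
    expect_lte(f[["LIF"]], f[["Q1"]])
  }
})

test_that("fence edge cases behave as documented", {
  f <- lower_inner_fence(rep(3.5, 10))
  expect_equal(f[["LIF"]], 3.5)       # IQR = 0
  expect_error(lower_inner_fence(1:3), ">= 4")
  # inflating Q3 with high outliers lowers the fence (Q1 is untouched)
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  f0 <- lower_inner_fence(base)
  f1 <- lower_inner_fence(c(1, 2, 3, 4, 5, 6, 1000, 2000))
  expect_equal(f1[["Q1"]], f0[["Q1"]])
  expect_lt(f1[["LIF"]], f0[["LIF"]])
})

test_that("nuclear contrast is scale-invariant and zero on flat regions", {
  img <- matrix(200, 64, 64)
  mask <- matrix(FALSE, 64, 64); mask[20:30, 20:30] <- TRUE
  expect_equal(nucleus_contrast(img, mask), 0)
  f <- render_field(phenotype_presets()$NT, 6, img_size = c(128, 128),
                    seed = 41)
  m <- f$truth$nucleus_labels == 1
  c1 <- nucleus_contrast(f$channels$DAPI, m)
  c2 <- nucleus_contrast(f$channels$DAPI * 7.3, m)
  expect_equal(c1, c2, tolerance = 1e-12)
  expect_error(nucleus_contrast(img, matrix(FALSE, 64, 64)), "empty")
})

test_that("defocus blur strictly reduces nuclear contrast", {
  sharp <- render_field(phenotype_presets()$NT, 10, img_size = c(160, 160),
                        seed = 42)
  blurred <- render_field(phenotype_presets()$NT, 10,
                          img_size = c(160, 160), blur_sigma = 4,
                          seed = 42)
  cfg <- screen_config()
  cs <- analyze_field(sharp, cfg)$contrasts
  cb <- analyze_field(blurred, cfg)$contrasts
  expect_gt(min(cs), max(cb))
})

test_that("the >50% rule is strict and zero-nucleus fields are flagged", {
  # pooled contrasts: sharp cluster at 1.0, defocused values at 0.5
  pool <- data.frame(
    field = c(rep(1, 10), rep(2, 10), rep(3, 80)),
    contrast = c(rep(0.5, 6), rep(1, 4),    # field 1: 6/10 below
                 rep(0.5, 5), rep(1, 5),    # field 2: 5/10 below
                 rep(1, 80)))
  res <- classify_fields_focus(pool, fields = 1:4)
  expect_equal(res$LIF, 1)
  ff <- res$fields
  expect_true(ff$out_of_focus[ff$field == 1])
  expect_false(ff$out_of_focus[ff$field == 2])   # exactly 50% is kept
  expect_false(ff$out_of_focus[ff$field == 3])
  expect_true(ff$out_of_focus[ff$field == 4])    # no nuclei
  expect_equal(ff$n_nuclei[ff$field == 4], 0)
})

test_that("simulated defocused fields are the ones flagged", {
  lay <- make_plate_layout(0, control_counts = c(NT = 2), seed = 51)
  keep <- lay$well[lay$role == "NT"]
  sens <- spec <- c(0, 0)
  for (w in seq_along(keep)) {
    lay1 <- lay
    lay1$role[lay1$role != "media" & lay1$well != keep[w]] <- "empty"
    sim <- simulate_screen(lay1, fields_per_well = 8,
                           mean_cells_per_field = 18, oof_frac = 0.25,
                           img_size = c(192, 192), seed = 60 + w)
    truth <- vapply(sim, function(f) f$truth$is_out_of_focus, logical(1))
    res <- analyze_well(sim, screen_config())
    called <- res$focus$fields$out_of_focus
    sens <- sens + c(sum(called & truth), sum(truth))
    spec <- spec + c(sum(!called & !truth), sum(!truth))
  }
  expect_equal(sens[1], sens[2])  # all defocused fields caught
  expect_equal(spec[1], spec[2])  # no sharp field flagged
})
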