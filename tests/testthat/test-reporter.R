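test_that("NT wells self-normalize to a median fold change of exactly 1", {
  lay <- make_plate_layout(30, seed = 21)
  tab <- simulate_reporter_plate(lay, cv = 0.1, seed = 22)
  norm <- normalize_reporter(tab)
  nt <- norm$role == "NT"
  expect_equal(median(norm$fold_change[nt]), 1, tolerance = 1e-12)
})

test_that("the viability ratio cancels proportional losses", {
  tab <- data.frame(
    well = c("B02", "B03", "B04", "B05", "B06"),
    role = c(rep("NT", 4), "sample"),
    gene = c(rep("NT", 4), "g1"), condition = "NoEGTA", barcode = "P",
    luminescence = c(1000, 1000, 1000, 1000, 500),
    viability = c(1000, 1000, 1000, 1000, 500))
  norm <- normalize_reporter(tab)
  expect_equal(norm$fold_change[norm$gene == "g1"], 1)
})

test_that("wells at the viability floor are excluded with a warning", {
  tab <- data.frame(
    well = sprintf("B%02d", 2:7), role = c(rep("NT", 4), "sample",
                                           "sample"),
    gene = c(rep("NT", 4), "g1", "g2"), condition = "NoEGTA",
    barcode = "P",
    luminescence = c(1000, 900, 1100, 1000, 800, 700),
    viability = c(1000, 1000, 1000, 1000, 0, 1000))
  expect_warning(norm <- normalize_reporter(tab), "floor")
  expect_true(is.na(norm$fold_change[norm$gene == "g1"]))
  expect_false(is.na(norm$fold_change[norm$gene == "g2"]))
  expect_error(suppressWarnings(normalize_reporter(
    transform(tab, viability = 0))), "NT wells")
})

test_that("simulated signaling suppression is recovered quantitatively", {
  lay <- make_plate_layout(0, control_counts = c(
    NT = 8, pos_ctrl_PSENEN = 8), condition = "EGTA", seed = 23)
  tab <- simulate_reporter_plate(lay, cv = 0.1, seed = 24)
  norm <- normalize_reporter(tab)
  ps <- norm$fold_change[norm$role == "pos_ctrl_PSENEN"]
  expect_equal(mean(ps), 0.2, tolerance = 0.05 / 0.2)
})

test_that("the 30% modulation rule is boundary-inclusive", {
  expect_equal(classify_signaling(c(0.65, 1.35, 1.2)),
               c("suppressor", "enhancer", "none"))
  expect_equal(classify_signaling(0.70), "suppressor")
  expect_equal(classify_signaling(1.30), "enhancer")
  expect_equal(classify_signaling(0.701), "none")
  # degenerate threshold: everything away from 1 is classified
  expect_equal(classify_signaling(c(0.99, 1.01), threshold = 0),
               c("suppressor", "enhancer"))
})

test_that("the EGTA assay window measures the stimulation factor", {
  lay0 <- make_plate_layout(0, control_counts = c(NT = 24),
                            condition = "NoEGTA", seed = 25)
  lay1 <- make_plate_layout(0, control_counts = c(NT = 24),
                            condition = "EGTA", seed = 25)
  tab <- rbind(simulate_reporter_plate(lay0, cv = 0.1, stim_factor = 5,
                                       seed = 26),
               simulate_reporter_plate(lay1, cv = 0.1, stim_factor = 5,
                                       seed = 27))
  norm <- normalize_reporter(tab)
  win <- assay_window(norm)
  expect_equal(win$window, 5, tolerance = 0.1)
  expect_true(win$valid)
  # identical +/- EGTA medians: window 1, invalid at the default minimum
  flat <- rbind(simulate_reporter_plate(lay0, cv = 0, stim_factor = 1,
                                        seed = 28),
                simulate_reporter_plate(lay1, cv = 0, stim_factor = 1,
                                        seed = 28))
  win_flat <- assay_window(normalize_reporter(flat))
  expect_equal(win_flat$window, 1)
  expect_false(win_flat$valid)
  # the window minimum is inclusive
  expect_true(assay_window(norm, stim_factor_min = win$window)$valid)
  expect_error(assay_window(norm[norm$condition == "EGTA", ]), "missing")
})

test_that("localization and signaling merge reproduces the bookkeeping", {
  confirmed <- data.frame(
    gene = sprintf("g%02d", 1:51), condition = "NoEGTA",
    phenotypic_class = "increased_intracellular")
  # 21 unstim-only, 8 stim-only, 10 both, 12 silent
  sig <- rbind(
    data.frame(gene = sprintf("g%02d", 1:21), condition = "NoEGTA",
               direction = "suppressor", fold_change = 0.5),
    data.frame(gene = sprintf("g%02d", 22:29), condition = "EGTA",
               direction = "suppressor", fold_change = 0.6),
    data.frame(gene = rep(sprintf("g%02d", 30:39), 2),
               condition = rep(c("NoEGTA", "EGTA"), each = 10),
               direction = "enhancer", fold_change = 1.6),
    data.frame(gene = sprintf("g%02d", 40:51), condition = "NoEGTA",
               direction = "none", fold_change = 1.05))
  res <- merge_localization_signaling(confirmed, sig)
  expect_equal(res$tally$n_confirmed, 51)
  expect_equal(res$tally$n_signaling_modulators, 39)
  expect_equal(res$tally$n_unstim_only, 21)
  expect_equal(res$tally$n_stim_only, 8)
  expect_equal(res$tally$n_both_conditions, 10)
  expect_equal(res$tally$pct_modulators, 76.5)
  expect_equal(res$tally$n_suppressors + res$tally$n_enhancers,
               res$tally$n_signaling_modulators)
  # empty signaling calls
  res0 <- merge_localization_signaling(
    confirmed, sig[0, ])
  expect_equal(res0$tally$n_signaling_modulators, 0)
  expect_equal(res0$tally$pct_modulators, 0)
})
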