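zrow <- function(gene = "g1", condition = "NoEGTA", role = "sample",
                 QC1 = 350, z_QC1 = 0, z_N1 = 0, z_N3 = 0, z_N4 = 0,
                 z_N5 = 0, z_N9 = 0) {
  data.frame(gene = gene, condition = condition, role = role, QC1 = QC1,
             z_QC1 = z_QC1, z_N1 = z_N1, z_N3 = z_N3, z_N4 = z_N4,
             z_N5 = z_N5, z_N9 = z_N9, stringsAsFactors = FALSE)
}

test_that("the viability gate catches cytotoxic wells", {
  z <- rbind(zrow("a", z_QC1 = -2.5), zrow("b", z_QC1 = -1),
             zrow("c", QC1 = 0, z_QC1 = 0), zrow("d", QC1 = 49))
  g <- viability_gate(z, z_viab = 2, min_cells = 50)
  expect_equal(g, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("simulated PLK1 wells are gated while NT wells survive", {
  lay <- make_plate_layout(280, control_counts = c(
    NT = 12, transfection_ctrl_PLK1 = 8, pos_ctrl_PSENEN = 4,
    no_siRNA = 4), seed = 13)
  fx <- simulate_well_features(lay, seed = 14)
  z <- plate_zscores(fx)
  z$QC1 <- z$QC1_NoOfAnalysedCells
  g <- viability_gate(z)
  plk <- z$role == "transfection_ctrl_PLK1"
  nt <- z$role == "NT"
  expect_gte(mean(g[plk]), 0.95)
  expect_lte(mean(g[nt]), 0.05)
})

test_that("hit classes follow the z-shift rules", {
  z <- rbind(
    zrow("quiet"),
    zrow("spots", z_N5 = 3),
    zrow("spots_pm", z_N5 = 3, z_N3 = -3),
    zrow("nuclear", z_N1 = 3),
    zrow("loss", z_N4 = -3),
    zrow("pm_only", z_N3 = -3),
    zrow("toxic", z_N9 = 5, z_QC1 = -4))
  gated <- viability_gate(z)
  h <- call_hits(z, gated, z_hit = 2)
  cls <- setNames(h$phenotypic_class, h$gene)
  expect_equal(unname(cls["quiet"]), "none")
  expect_equal(unname(cls["spots"]), "increased_intracellular")
  expect_equal(unname(cls["spots_pm"]), "altered_PM_and_intracellular")
  expect_equal(unname(cls["nuclear"]), "increased_nuclear")
  expect_equal(unname(cls["loss"]), "decreased_total")
  hit <- setNames(h$hit, h$gene)
  expect_false(hit[["quiet"]])
  expect_true(hit[["spots"]])
  expect_true(hit[["spots_pm"]])
  expect_true(hit[["nuclear"]])
  expect_false(hit[["loss"]])     # general loss excluded from hit list
  expect_false(hit[["pm_only"]])
  expect_false(hit[["toxic"]])    # gated by viability
  expect_true(all(!h$hit | h$phenotypic_class != "none"))
})

test_that("condition tallies partition the hit union", {
  a <- call_hits(do.call(rbind, lapply(c("g1", "g2", "g3"), function(g)
    zrow(g, z_N5 = 3))))
  b <- call_hits(do.call(rbind, lapply(c("g3", "g4"), function(g)
    zrow(g, condition = "EGTA", z_N5 = 3))))
  t1 <- combine_conditions(a, b)
  expect_equal(t1$n_primary_hits, 4)
  expect_equal(t1$n_only_NoEGTA, 2)
  expect_equal(t1$n_only_EGTA, 1)
  expect_equal(t1$n_both, 1)
  expect_equal(t1$n_only_NoEGTA + t1$n_only_EGTA + t1$n_both,
               t1$n_primary_hits)
  # identical sets: everything lands in "both"
  t2 <- combine_conditions(a, transform(a, condition = "EGTA"))
  expect_equal(t2$n_both, 3)
  expect_equal(t2$n_only_NoEGTA + t2$n_only_EGTA, 0)
})

test_that("screen reconciliation requires class and condition agreement", {
  p <- call_hits(rbind(zrow("g1", z_N5 = 3), zrow("g2", z_N1 = 3),
                       zrow("g3", z_N5 = 3, z_N3 = -3)))
  s_same <- call_hits(rbind(zrow("g1", z_N5 = 3), zrow("g2", z_N1 = 3),
                            zrow("g3", z_N5 = 3, z_N3 = -3)))
  expect_equal(sort(reconcile_screens(p, s_same)$gene),
               c("g1", "g2", "g3"))
  # class flip: g2 now spots instead of nuclear -> not confirmed
  s_flip <- call_hits(rbind(zrow("g1", z_N5 = 3), zrow("g2", z_N5 = 3)))
  expect_equal(reconcile_screens(p, s_flip)$gene, "g1")
  # condition flip -> not confirmed
  s_cond <- call_hits(zrow("g1", condition = "EGTA", z_N5 = 3))
  expect_equal(nrow(reconcile_screens(p, s_cond)), 0)
})

test_that("two-reagent confirmation improves precision over the primary", {
  set.seed(77)
  n_true <- 15; n_null <- 85
  genes <- c(sprintf("hit%02d", 1:n_true), sprintf("neg%02d", 1:n_null))
  better <- 0; trials <- 30
  for (i in 1:trials) {
    sim_screen <- function() {
      z5 <- c(rnorm(n_true, 4, 1), rnorm(n_null, 0, 1))
      # 15% reagent-specific spurious shifts among the nulls
      fp <- runif(n_null) < 0.15
      z5[n_true + which(fp)] <- rnorm(sum(fp), 4, 1)
      do.call(rbind, lapply(seq_along(genes), function(k)
        zrow(genes[k], z_N5 = z5[k])))
    }
    p <- call_hits(sim_screen())
    s <- call_hits(sim_screen())
    conf <- reconcile_screens(p, s)
    prec_p <- mean(grepl("^hit", p$gene[p$hit]))
    prec_c <- mean(grepl("^hit", conf$gene))
    if (!is.nan(prec_c) && prec_c > prec_p) better <- better + 1
  }
  expect_gte(better / trials, 0.9)
})

test_that("Welch t tests match a first-principles oracle", {
  a <- c(1.1, 2.3, 3.7); b <- c(2.0, 4.1, 5.2)
  got <- ttest_stars(a, b)
  ora <- oracle_welch(a, b)
  expect_equal(got$t, ora$t, tolerance = 1e-9)
  expect_equal(got$p, ora$p, tolerance = 1e-9)
  same <- ttest_stars(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$label, "ns")
  expect_equal(ttest_stars(rep(2, 3), rep(2, 3))$label, "ns")
  expect_equal(ttest_stars(rep(2, 3), rep(5, 3))$label, "****")
})

test_that("star tiers follow the printed thresholds", {
  expect_equal(stars_label(0.06), "ns")
  expect_equal(stars_label(0.05), "ns")
  expect_equal(stars_label(0.049), "*")
  expect_equal(stars_label(0.009), "**")
  expect_equal(stars_label(0.0009), "***")
  expect_equal(stars_label(0.00009), "****")
})
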