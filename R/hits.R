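#' Viability gate
#'
#' Excludes wells with marked cytotoxicity before localization hit
#' calling: a well is gated when its cell-count z-score falls at or below
#' `-z_viab` or fewer than `min_cells` cells were analysed. The PLK1
#' cytotoxic transfection control must be caught by this gate for a run
#' to be considered valid.
#'
#' @param z table with `z_QC1` and `QC1` columns (e.g. from
#'   [average_replicates()]).
#' @param z_viab viability z threshold (positive).
#' @param min_cells minimum analysed cells.
#' @return Logical vector, `TRUE` = excluded.
#' @export
viability_gate <- function(z, z_viab = 2, min_cells = 50) {
  stopifnot("z_QC1" %in% names(z), "QC1" %in% names(z))
  z$z_QC1 <= -z_viab | z$QC1 < min_cells
}

#' Call localization hits and assign phenotypic classes
#'
#' A knockdown is considered to affect a parameter when it shifts the
#' z-score beyond `z_hit` in the relevant direction. Classes: spots
#' parameters up (`z_N5` or `z_N9` >= z_hit) give
#' `increased_intracellular`, additionally membrane down (`z_N3` <=
#' -z_hit) gives `altered_PM_and_intracellular`; nuclear up alone gives
#' `increased_nuclear`; total signal down alone gives `decreased_total`,
#' which is reported but excluded from the hit list (general loss of
#' NOTCH1 signal); everything else is `none`. Viability-gated wells are
#' never hits.
#'
#' @param z replicate-averaged z table ([average_replicates()]).
#' @param gated logical vector from [viability_gate()] (recycled FALSE if
#'   omitted).
#' @param z_hit hit threshold on |z|.
#' @return `data.frame` per row of `z`: `gene`, `condition`, `hit`,
#'   `phenotypic_class`, `viability_excluded`, and the driving z-scores.
#' @export
call_hits <- function(z, gated = NULL, z_hit = 2) {
  if (is.null(gated)) gated <- rep(FALSE, nrow(z))
  stopifnot(length(gated) == nrow(z))
  spots_up <- z$z_N5 >= z_hit | z$z_N9 >= z_hit
  pm_down <- z$z_N3 <= -z_hit
  nuc_up <- z$z_N1 >= z_hit
  total_down <- z$z_N4 <= -z_hit
  cls <- ifelse(spots_up & pm_down, "altered_PM_and_intracellular",
         ifelse(spots_up, "increased_intracellular",
         ifelse(nuc_up, "increased_nuclear",
         ifelse(total_down, "decreased_total", "none"))))
  cls[is.na(cls)] <- "none"
  hit <- cls %in% c("increased_intracellular",
                    "altered_PM_and_intracellular",
                    "increased_nuclear") & !gated
  data.frame(gene = z$gene, condition = z$condition, role = z$role,
             hit = hit, phenotypic_class = cls,
             viability_excluded = gated,
             z_N1 = z$z_N1, z_N3 = z$z_N3, z_N4 = z$z_N4, z_N5 = z$z_N5,
             z_N9 = z$z_N9, z_QC1 = z$z_QC1,
             stringsAsFactors = FALSE)
}

#' Combine hit calls from the two stimulation conditions
#'
#' Partitions hit genes into condition-exclusive and shared groups; the
#' union is the primary hit count.
#'
#' @param hits_noegta,hits_egta hit tables from [call_hits()] for the
#'   unstimulated and EGTA-stimulated analyses.
#' @return List (`screen_tally`): `n_screened`, `n_primary_hits`,
#'   `n_only_NoEGTA`, `n_only_EGTA`, `n_both`, `class_counts`.
#' @export
combine_conditions <- function(hits_noegta, hits_egta) {
  a <- unique(hits_noegta$gene[hits_noegta$hit])
  b <- unique(hits_egta$gene[hits_egta$hit])
  screened <- union(unique(hits_noegta$gene), unique(hits_egta$gene))
  both <- intersect(a, b)
  tally <- list(
    n_screened = length(screened),
    n_primary_hits = length(union(a, b)),
    n_only_NoEGTA = length(setdiff(a, b)),
    n_only_EGTA = length(setdiff(b, a)),
    n_both = length(both),
    class_counts = table(c(
      hits_noegta$phenotypic_class[hits_noegta$hit],
      hits_egta$phenotypic_class[hits_egta$hit])))
  structure(tally, class = "screen_tally")
}

#' Reconcile primary and validation screens
#'
#' A primary hit is confirmed when the validation screen (independent
#' silencing reagents) calls it a hit with the same phenotypic class in
#' the same condition.
#'
#' @param primary,secondary hit tables from [call_hits()].
#' @return `data.frame` of confirmed calls (`gene`, `condition`,
#'   `phenotypic_class`).
#' @export
reconcile_screens <- function(primary, secondary) {
  p <- primary[primary$hit, c("gene", "condition", "phenotypic_class")]
  s <- secondary[secondary$hit, c("gene", "condition", "phenotypic_class")]
  merge(p, s, by = c("gene", "condition", "phenotypic_class"))
}

#' Welch t test with significance stars
#'
#' Unpaired two-tailed Welch t test with the star tiers used in the
#' figures: ns >= 0.05, * < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return List `t`, `p`, `label`.
#' @export
ttest_stars <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, label = "ns"))
    return(list(t = Inf * sign(mean(a) - mean(b)), p = 0, label = "****"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       label = stars_label(tt$p.value))
}

#' @rdname ttest_stars
#' @param p p value.
#' @export
stars_label <- function(p) {
  if (p >= 0.05) "ns"
  else if (p >= 0.01) "*"
  else if (p >= 0.001) "**"
  else if (p >= 0.0001) "***"
  else "****"
}
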