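#' Viability-normalize reporter readouts
#'
#' Divides luminescence by resazurin viability fluorescence (the
#' ratiometric correction for proliferation effects of the knockdown) and
#' expresses each well as a fold change over the median normalized value
#' of the non-targeting wells of the same plate x condition. By
#' construction the NT median fold change is exactly 1 on every plate.
#'
#' @param wells reporter table (`well`, `role`, `gene`, `condition`,
#'   `barcode`, `luminescence`, `viability`).
#' @param viability_floor wells at or below this viability are excluded
#'   (with a warning) instead of producing unstable ratios.
#' @param min_nt minimum NT wells required per plate.
#' @return Input table with `normalized` and `fold_change` columns
#'   (`NA` for excluded wells).
#' @export
normalize_reporter <- function(wells, viability_floor = 0, min_nt = 4) {
  stopifnot(all(c("role", "condition", "barcode", "luminescence",
                  "viability") %in% names(wells)))
  excl <- wells$viability <= viability_floor
  if (any(excl))
    warning(sum(excl), " well(s) excluded: viability at or below floor (",
            viability_floor, ")")
  wells$normalized <- ifelse(excl, NA_real_,
                             wells$luminescence / wells$viability)
  wells$fold_change <- NA_real_
  grp <- interaction(wells$barcode, wells$condition, drop = TRUE)
  for (g in levels(grp)) {
    sel <- grp == g
    nt <- sel & wells$role == "NT" & !excl
    if (sum(nt) < min_nt)
      stop("plate group ", g, " has ", sum(nt), " usable NT wells (< ",
           min_nt, ")")
    ref <- stats::median(wells$normalized[nt])
    wells$fold_change[sel] <- wells$normalized[sel] / ref
  }
  wells
}

#' Classify reporter fold changes
#'
#' The screen's modulation rule: a knockdown alters Notch signaling when
#' its viability-normalized reporter output changes by at least
#' `threshold` (default 30%, boundary inclusive): fold <= 1 - threshold is
#' a suppressor, fold >= 1 + threshold an enhancer.
#'
#' @param fold_change numeric vector of fold changes (> 0).
#' @param threshold modulation threshold (0.30 = 30%).
#' @return Character vector `"suppressor"` / `"enhancer"` / `"none"`.
#' @export
classify_signaling <- function(fold_change, threshold = 0.30) {
  stopifnot(all(is.na(fold_change) | fold_change > 0))
  ifelse(is.na(fold_change), NA_character_,
  ifelse(fold_change <= 1 - threshold, "suppressor",
  ifelse(fold_change >= 1 + threshold, "enhancer", "none")))
}

#' EGTA assay window of a reporter plate pair
#'
#' Ratio of the median normalized NT signal under EGTA stimulation to the
#' unstimulated median — the fold induction of the reporter. The plate
#' pair is valid when the window reaches `stim_factor_min` (inclusive).
#'
#' @param wells normalized reporter table covering both conditions
#'   (from [normalize_reporter()]).
#' @param stim_factor_min minimum acceptable window.
#' @return List `window`, `valid`.
#' @export
assay_window <- function(wells, stim_factor_min = 2) {
  for (cond in c("NoEGTA", "EGTA"))
    if (!any(wells$condition == cond & wells$role == "NT"))
      stop("missing NT wells for condition ", cond)
  med <- function(cond)
    stats::median(wells$normalized[wells$condition == cond &
                                     wells$role == "NT"], na.rm = TRUE)
  window <- med("EGTA") / med("NoEGTA")
  list(window = window, valid = window >= stim_factor_min)
}

#' Merge localization hits with signaling calls
#'
#' Joins the confirmed localization hits with the reporter signaling
#' calls and tallies the combined bookkeeping: number of modulators,
#' suppressors/enhancers, per-condition breakdown, and the percentage of
#' confirmed localization hits that modulate signaling.
#'
#' A gene is a modulator if its signaling direction is not `"none"` in at
#' least one condition; its overall direction is taken from the condition
#' with the larger deviation of fold change from 1.
#'
#' @param confirmed confirmed hits (`gene`, `condition`,
#'   `phenotypic_class`), e.g. from [reconcile_screens()].
#' @param signaling per-gene x condition signaling calls (`gene`,
#'   `condition`, `direction`, `fold_change`).
#' @return List with `genes` (joint per-gene table) and `tally`
#'   (`n_confirmed`, `n_signaling_modulators`, `n_suppressors`,
#'   `n_enhancers`, `n_unstim_only`, `n_stim_only`, `n_both_conditions`,
#'   `pct_modulators`).
#' @export
merge_localization_signaling <- function(confirmed, signaling) {
  genes <- unique(confirmed$gene)
  rows <- lapply(genes, function(g) {
    sg <- signaling[signaling$gene == g & !is.na(signaling$direction), ,
                    drop = FALSE]
    mod_conds <- sg$condition[sg$direction != "none"]
    direction <- "none"
    if (length(mod_conds)) {
      smod <- sg[sg$direction != "none", , drop = FALSE]
      direction <- smod$direction[which.max(abs(smod$fold_change - 1))]
    }
    data.frame(gene = g,
               phenotypic_class = paste(
                 unique(confirmed$phenotypic_class[confirmed$gene == g]),
                 collapse = ";"),
               direction = direction,
               modulates_unstim = "NoEGTA" %in% mod_conds,
               modulates_stim = "EGTA" %in% mod_conds,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mod <- !is.null(tab) && nrow(tab) > 0
  n_mod <- if (mod) sum(tab$direction != "none") else 0
  tally <- list(
    n_confirmed = length(genes),
    n_signaling_modulators = n_mod,
    n_suppressors = if (mod) sum(tab$direction == "suppressor") else 0,
    n_enhancers = if (mod) sum(tab$direction == "enhancer") else 0,
    n_unstim_only = if (mod) sum(tab$modulates_unstim &
                                   !tab$modulates_stim) else 0,
    n_stim_only = if (mod) sum(!tab$modulates_unstim &
                                 tab$modulates_stim) else 0,
    n_both_conditions = if (mod) sum(tab$modulates_unstim &
                                       tab$modulates_stim) else 0,
    pct_modulators = if (length(genes))
      fraction_pct(n_mod, length(genes), 1) else 0)
  list(genes = tab, tally = tally)
}
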