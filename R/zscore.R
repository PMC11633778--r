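FEATURE_COLS <- c(QC1 = "QC1_NoOfAnalysedCells", N1 = "N1_NucNotch",
                  N3 = "N3_MembNotch", N4 = "N4_CellNotch",
                  N5 = "N5_PercentOfCellsWithSpots",
                  N9 = "N9_NoOfSpotsPerCell")

#' Per-plate z-scores of the well parameters
#'
#' Standardises every well parameter within each plate x condition group.
#' The default robust method uses the median and the scaled MAD
#' (`1.4826 * MAD`) of the *sample* wells as reference population — the
#' standard choice for arrayed screens where most genes are inert; a
#' classic mean/SD method and an NT-referenced variant are selectable.
#' EGTA and NoEGTA plates are standardised independently (they never share
#' a barcode x condition group).
#'
#' @param features per-well feature table (see
#'   [simulate_well_features()] / [analyze_screen()] for the columns).
#' @param method `"robust"` (median/MAD) or `"classic"` (mean/SD).
#' @param reference `"sample"` (default) or `"NT"` wells.
#' @param min_reference minimum reference wells per plate.
#' @return The input with `z_QC1`, `z_N1`, `z_N3`, `z_N4`, `z_N5`, `z_N9`
#'   columns appended; attribute `"reference_stats"` holds the per-plate
#'   center/scale used.
#' @export
plate_zscores <- function(features, method = c("robust", "classic"),
                          reference = c("sample", "NT"),
                          min_reference = 8) {
  method <- match.arg(method)
  reference <- match.arg(reference)
  stopifnot(all(FEATURE_COLS %in% names(features)))
  grp <- interaction(features$barcode, features$condition, drop = TRUE)
  stats_rows <- list()
  for (p in names(FEATURE_COLS)) {
    col <- FEATURE_COLS[[p]]
    features[[paste0("z_", p)]] <- NA_real_
  }
  for (g in levels(grp)) {
    sel <- grp == g
    ref <- sel & features$role == if (reference == "sample") "sample"
                                  else "NT"
    if (sum(ref) < min_reference)
      stop("plate group ", g, " has ", sum(ref), " reference wells (< ",
           min_reference, ")")
    for (p in names(FEATURE_COLS)) {
      x <- features[[FEATURE_COLS[[p]]]]
      xr <- x[ref]
      xr <- xr[!is.na(xr)]
      if (method == "robust") {
        center <- stats::median(xr)
        scale <- stats::mad(xr)  # already scaled by 1.4826
        if (scale == 0) {
          warning("MAD = 0 for ", p, " on plate ", g,
                  "; falling back to SD")
          scale <- stats::sd(xr)
        }
      } else {
        center <- mean(xr)
        scale <- stats::sd(xr)
      }
      if (is.na(scale) || scale == 0) {
        warning("zero scale for ", p, " on plate ", g, "; z set to 0")
        z <- ifelse(is.na(x), NA_real_, 0)
      } else {
        z <- (x - center) / scale
      }
      features[[paste0("z_", p)]][sel] <- z[sel]
      stats_rows[[paste0(g, ".", p)]] <-
        data.frame(group = g, parameter = p, center = center,
                   scale = scale)
    }
  }
  attr(features, "reference_stats") <- do.call(rbind, stats_rows)
  features
}

#' Average z-scores across replicate plates
#'
#' The screen ran triplicate plates per condition; z-scores are computed
#' per plate and averaged per gene x condition before hit calling, which
#' buffers single-plate artifacts.
#'
#' @param z z-scored feature table from [plate_zscores()].
#' @return `data.frame` keyed by `gene`, `condition`, `role` with averaged
#'   z columns, `n_replicates`, and the replicate-mean `QC1`.
#' @export
average_replicates <- function(z) {
  zcols <- paste0("z_", names(FEATURE_COLS))
  stopifnot(all(zcols %in% names(z)))
  key <- interaction(z$gene, z$condition, z$role, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    s <- z[which(key == k), , drop = FALSE]
    out <- data.frame(gene = s$gene[1], condition = s$condition[1],
                      role = s$role[1], n_replicates = nrow(s),
                      QC1 = mean(s$QC1_NoOfAnalysedCells),
                      stringsAsFactors = FALSE)
    for (cc in zcols) out[[cc]] <- mean(s[[cc]], na.rm = TRUE)
    out
  })
  do.call(rbind, rows)
}
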