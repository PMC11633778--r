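#' Screen analysis configuration
#'
#' Bundles every tunable of the pipeline with its default, validated up
#' front. The configuration (and its hash) is stamped into output tables
#' so downstream stages can refuse to mix results produced under
#' different settings.
#'
#' @param ring_width_px membrane ring width (px).
#' @param bg_radius background-opening radius (px).
#' @param min_nucleus_area minimum nucleus area (px).
#' @param min_area,max_area cell area bounds (px^2).
#' @param min_solidity minimum cell solidity.
#' @param sat_frac max fraction of saturated pixels per cell.
#' @param fence_k Tukey fence multiplier.
#' @param focus_min_frac out-of-focus fraction threshold (strict).
#' @param snr_threshold,spot_sigma_px,spot_min puncta detection settings.
#' @param z_hit,z_viab hit-calling and viability z thresholds.
#' @param min_cells minimum analysed cells per well.
#' @param modulation_threshold reporter modulation rule (0.30 = 30%).
#' @param stim_factor_min minimum EGTA assay window.
#' @return Classed list `screen_config`.
#' @export
screen_config <- function(ring_width_px = 3, bg_radius = 96,
                          min_nucleus_area = 40,
                          min_area = 200, max_area = 20000,
                          min_solidity = 0.8, sat_frac = 0.005,
                          fence_k = 1.5, focus_min_frac = 0.5,
                          snr_threshold = 5, spot_sigma_px = 1.5,
                          spot_min = 2,
                          z_hit = 2, z_viab = 2, min_cells = 50,
                          modulation_threshold = 0.30,
                          stim_factor_min = 2) {
  cfg <- list(ring_width_px = ring_width_px, bg_radius = bg_radius,
              min_nucleus_area = min_nucleus_area,
              min_area = min_area, max_area = max_area,
              min_solidity = min_solidity, sat_frac = sat_frac,
              fence_k = fence_k, focus_min_frac = focus_min_frac,
              snr_threshold = snr_threshold,
              spot_sigma_px = spot_sigma_px, spot_min = spot_min,
              z_hit = z_hit, z_viab = z_viab, min_cells = min_cells,
              modulation_threshold = modulation_threshold,
              stim_factor_min = stim_factor_min)
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(ring_width_px >= 0, "ring_width_px >= 0")
  chk(bg_radius >= 1, "bg_radius >= 1")
  chk(min_area >= 0 && max_area > min_area, "0 <= min_area < max_area")
  chk(min_solidity >= 0 && min_solidity <= 1, "min_solidity in [0,1]")
  chk(sat_frac >= 0 && sat_frac <= 1, "sat_frac in [0,1]")
  chk(fence_k > 0, "fence_k > 0")
  chk(focus_min_frac >= 0 && focus_min_frac <= 1,
      "focus_min_frac in [0,1]")
  chk(snr_threshold >= 0 && spot_sigma_px > 0 && spot_min >= 1,
      "spot parameters")
  chk(z_hit > 0 && z_viab > 0, "z thresholds > 0")
  chk(min_cells >= 0, "min_cells >= 0")
  chk(modulation_threshold >= 0, "modulation_threshold >= 0")
  chk(stim_factor_min > 0, "stim_factor_min > 0")
  structure(cfg, class = "screen_config")
}

#' @rdname screen_config
#' @param cfg a `screen_config`.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "screen_config"))
  fnv1a32(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}

#' Write / read a results CSV stamped with the configuration hash
#'
#' Output tables carry a `# config_hash:` comment header; readers verify
#' the hash when asked, so tables produced under different configurations
#' are not silently combined.
#'
#' @param df table to write.
#' @param path file path.
#' @param cfg the `screen_config` the table was produced under.
#' @param expect_hash optional hash that the file must carry.
#' @return The table (reader) or the path, invisibly (writer).
#' @export
write_results_csv <- function(df, path, cfg = screen_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", config_hash(cfg)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path, expect_hash = NULL) {
  if (!file.exists(path)) stop("results file not found: ", path)
  first <- readLines(path, n = 1)
  hash <- sub("^# config_hash: ", "", first)
  if (!grepl("^# config_hash: ", first)) hash <- NA_character_
  if (!is.null(expect_hash) && (is.na(hash) || hash != expect_hash))
    stop("config hash mismatch in ", path, ": expected ", expect_hash,
         ", found ", hash)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "config_hash") <- hash
  df
}
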