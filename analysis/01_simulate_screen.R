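#!/usr/bin/env Rscript
# Simulate a small demonstration plate of the NOTCH1 localization screen:
# a 384-well layout with media ring and control wells, and 3-channel
# field images (DAPI / phalloidin / NOTCH1) with ground truth for a
# handful of wells, including two planted intracellular-spots phenotypes
# and the PLK1 cytotoxic transfection control. Outputs feed
# 02_segment_features.R through the package's TIFF/CSV contracts.

library(notchhcs)

out_dir <- "results"
field_dir <- file.path(out_dir, "fields")
dir.create(field_dir, showWarnings = FALSE, recursive = TRUE)

ph <- phenotype_presets()
layout <- make_plate_layout(
  6, control_counts = c(NT = 3, transfection_ctrl_PLK1 = 2),
  condition = "NoEGTA", barcode = "DEMO01", seed = 11)
write_layout_csv(layout, file.path(out_dir, "layout.csv"))

# genes 1 and 2 carry the endo-lysosomal spots phenotype
ph_map <- list(gene0001 = ph$spots, gene0002 = ph$spots)

fields <- simulate_screen(layout, phenotype_map = ph_map,
                          fields_per_well = 4, mean_cells_per_field = 18,
                          oof_frac = 0.25, img_size = c(192, 192),
                          seed = 12)
for (f in fields) write_field_tiff(f, field_dir)

n_wells <- length(unique(vapply(fields, `[[`, "", "well")))
cat("Simulated", length(fields), "fields over", n_wells, "wells;",
    "1 in 4 fields per well rendered out of focus (sigma = 4 px).\n")
cat("Layout written to", file.path(out_dir, "layout.csv"),
    "; images + truth sidecars under", field_dir, "\n")
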