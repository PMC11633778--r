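Package: notchhcs
Title: High-Content RNAi Screen Analysis of NOTCH1 Subcellular Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for arrayed RNAi high-content screens of
    NOTCH1 subcellular localization and signaling in MCF10A cells. Provides a
    synthetic plate and field-image generator with ground truth, seeded
    watershed segmentation of nuclei, cells and compartments from
    DAPI/phalloidin/NOTCH1 channels, out-of-focus field quality control by
    Tukey fences on nuclear contrast, per-well phenotype parameters, robust
    per-plate z-score hit calling with phenotypic classification,
    viability-normalized luciferase reporter analysis, and ComDet-style spot
    detection with distance-bounded colocalization for confocal validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
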