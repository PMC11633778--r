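---
title: "Methods: high-content analysis of NOTCH1 localization screens"
author: "notchhcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-content analysis of NOTCH1 localization screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchhcs)
```

# The assay and what the package computes

An arrayed RNAi screen in MCF10A cells asks, gene by gene, whether a
knockdown changes where the NOTCH1 receptor sits in the cell: on the
plasma membrane, diffusely in the cytosol, in intracellular puncta
(endo-lysosomal compartments), or in the nucleus. Cells are reverse
transfected on 384-well plates, fixed, and imaged in three channels
(DAPI for nuclei, phalloidin for the actin cortex, immunofluorescent
NOTCH1), eight fields per well. Duplicated plate sets are analysed with
and without EGTA stimulation, a Ca^2+^-chelation pulse that destabilizes
the NOTCH1 heterodimerization domain and mimics ligand-dependent
activation; the two conditions are analysed independently throughout.

The package implements the full analysis chain:

1. **Synthetic data** (`make_plate_layout`, `render_field`,
   `simulate_screen`, `simulate_reporter_plate`,
   `simulate_well_features`) — no images from the original screen are
   publicly deposited, so every downstream stage is exercised against a
   generator with exact ground truth.
2. **Imaging** (`correct_background`, `segment_nuclei`, `segment_cells`,
   `derive_compartments`, `qc_cells`, `nucleus_contrast`,
   `lower_inner_fence`, `classify_fields_focus`) — the per-field image
   script: background correction, nucleus segmentation, seeded
   watershed on the inverted phalloidin channel, compartment masks,
   cell exclusion rules, and out-of-focus field QC.
3. **Features** (`detect_spots`, `measure_cells`, `aggregate_well`) —
   per-cell compartment intensities and puncta, aggregated to the named
   well parameters `QC1_NoOfAnalysedCells`, `N1_NucNotch`,
   `N3_MembNotch`, `N4_CellNotch`, `N5_PercentOfCellsWithSpots`,
   `N9_NoOfSpotsPerCell`.
4. **Screen statistics** (`plate_zscores`, `average_replicates`,
   `viability_gate`, `call_hits`, `combine_conditions`,
   `reconcile_screens`, `ttest_stars`) — per-plate robust z-scores,
   viability gating, phenotypic classification, condition tallies and
   primary/validation reconciliation.
5. **Reporter** (`normalize_reporter`, `classify_signaling`,
   `assay_window`, `merge_localization_signaling`) — the RBPJ-luciferase
   secondary screen with resazurin viability normalization and the
   inclusive 30% modulation rule.
6. **Colocalization** (`comdet_detect`, `colocalize`, `percent_intdens`,
   `roi_intdens`, `summarize_replicates`) — the confocal validation
   quantification (SNR-style intensity threshold 4, 2 px maximum
   colocalization distance, %IntDens ROI arithmetic, and the
   five-ROIs-in-five-images validity rule).

The numbered scripts under `analysis/` run these stages as a narrative
workflow and write their tables under `results/`.

# Plate geometry and controls

A 384-well plate (16 × 24) carries media in the entire outer ring — 76
wells by the border count — leaving 308 inner wells for samples and
controls. Every plate carries at least 8 non-targeting (NT) wells, and
at least 4 wells each of no-siRNA, PSENEN knockdown (positive signaling
control) and PLK1 knockdown (cytotoxic transfection control). Control
placement is a seeded shuffle over the inner wells. A gene occupies at
most one sample well per plate; a screen of more genes than fit on one
plate uses a plate set.

# The synthetic field model

`render_field` draws what a 20× widefield image of a confluent MCF10A
monolayer needs to exercise the pipeline, not a photorealistic
microscope simulation:

* **Cells.** Nucleus centers are placed by rejection sampling with a
  minimum separation of 20 px; territories are the Voronoi partition of
  the centers clipped at a 30 px radius (cell-free background remains
  where centers are sparse). Cell counts are drawn per *well* (Poisson
  around `mean_cells_per_field` × the phenotype's viability
  multiplier): fields of one confluent well sample the same monolayer,
  so counts vary between wells rather than within them.
* **DAPI.** Elliptical nuclei (semi-axes 6–7 px at the default
  0.65 µm/px) with a peaked radial profile multiplied by pixel-scale
  chromatin speckle (SD 1.0 of the mean). The speckle matters: at this
  pixel size chromatin granularity is sub-pixel, and it is precisely
  the structure that defocus destroys first — the nuclear-contrast QC
  below depends on it (see *Out-of-focus QC*).
* **Phalloidin.** A moderate uniform fill inside cells with a bright
  2 px cortical ridge wherever two territories (or a territory and the
  background) meet — the inverted-watershed segmentation problem.
* **NOTCH1.** Each cell receives a fixed signal budget (3×10^5 DN)
  split across the membrane ring, cytosol and nucleus according to its
  phenotype's fractions, plus Poisson(`spot_rate`) Gaussian puncta
  (σ = 1.5 px) at random cytosolic positions.
* **Camera.** Poisson shot noise (gain 1) plus Gaussian read noise
  (SD 10 DN), clipped to the 16-bit range. Out-of-focus fields get a
  Gaussian defocus blur (σ = 4 px by default, flagged at σ ≥ 3) applied
  to all channels before the noise.

Ground truth (label images, spot coordinates, per-cell compartment
signal sums, blur flags) rides along with every field. What the model
deliberately omits: illumination gradients beyond an additive test
gradient, 3-D structure, mitotic/apoptotic morphologies, staining
variability between wells, and optical crosstalk. Passing tests on this
generator therefore demonstrate that the *algorithms* recover known
truth under realistic noise — not that the pipeline is robust to every
artifact of real microscopy.

A second, purely statistical generator (`simulate_well_features`) maps
phenotypes directly to expected well parameters and adds Gaussian
well-to-well noise. It exists so hit-calling power studies can run at
full screen scale (hundreds of wells, triplicates, two conditions) in
seconds; the image-based path validates the same feature definitions at
small scale.

# Imaging choices

**Background correction** subtracts a per-channel morphological-opening
(rolling-ball) estimate. The structuring radius defaults to 96 px —
deliberately much larger than one cell. In a confluent monolayer the
cell carpet is quasi-continuous: with a cell-sized radius the opening
absorbs the carpet itself into the "background" and flattens every cell
interior to zero. The estimate is computed on a downsampled copy with
edge-replication padding (no border bias) and resized back; correction
is idempotent to well under 1%.

**Nucleus segmentation** is Otsu thresholding of a σ = 1 smoothed copy
(so chromatin speckle cannot fragment the mask; the raw channel is left
untouched for the contrast QC), hole filling, a distance-transform
watershed to split touching nuclei, and a minimum-area filter (40 px).
Two guards make blank fields well-behaved: a constant image yields no
nuclei, and the Otsu threshold must stand at least 3 background SDs
above the background mean — otherwise the "threshold" is splitting
noise and the field is declared empty.

**Cell segmentation** inverts the phalloidin channel so cells become
bright basins with low values along the cortical ridges and floods from
the nucleus seeds (`EBImage::propagate`, a seeded watershed on an
intensity-weighted geodesic metric). Foreground is Otsu-estimated with
a second pass when the first threshold isolates only the ridges (their
extreme intensity dominates the between-class variance). Foreground not
reached from any seed, and everything below the foreground threshold,
forms the excluded cell-free region.

**Compartments.** The membrane ring is the inner band of
`ring_width_px` (default 3) pixels along the cell boundary — the image
edge counts as boundary for clipped cells; the nucleus is clipped to
its cell; the cytosol is the remainder. The three masks partition each
cell exactly, which makes the area-weighted mean identity
(`N4` vs compartments) an algebraic invariant rather than an
approximation.

**Cell exclusion** follows the screen's rules: border contact, area
outside [200, 20000] px², >0.5% saturated pixels in DAPI or NOTCH1,
and malformed cells (no seeding nucleus, or solidity < 0.8 against the
convex hull).

# Out-of-focus QC

Per nucleus, contrast is the coefficient of variation of DAPI
intensities over the nucleus dilated by 2 px (the dilation takes in the
steep nuclear edge). CV is intensity-scale invariant and provably
decreases under blur. Per well, the Tukey lower inner fence
`LIF = Q1 − 1.5·(Q3 − Q1)` (type-7 quantiles) is computed over the
contrasts of *all* nuclei in the well; a field is discarded when
strictly more than 50% of its nuclei fall below the LIF. Fields with no
detected nuclei are discarded too (they contribute nothing
analysable).

One property of this construction is worth stating openly: with
exactly 2 of 8 fields defocused, a quarter of the well's nuclei belong
to the low-contrast cluster, and Q1 sits at the boundary between the
clusters. The fence then only lands above the defocused cluster when
the contrast gap is large compared with the sharp cluster's spread
(roughly: gap > 9 within-cluster SDs). Smooth, textureless nuclei do
not produce such a gap — defocus merely softens their edges — which is
why the generator's chromatin speckle is not a cosmetic choice: fine
texture collapses under a σ = 4 px blur (contrast ≈ 1.2 → ≈ 0.45) while
the CV of a sharp textured nucleus is estimated from ~300 pixels and is
correspondingly tight. Under these conditions the rule reaches
sensitivity and specificity ≥ 0.95 over 50 simulated wells. At blur
σ < 2 px, or if defocused fields were the majority, the fence would
degrade gracefully toward missing them — a limitation inherited from
the published rule, not an implementation artifact.

# Features and spot detection

Compartment intensities are reported as means (totals are also
emitted), making features robust to cell-size differences; whether the
original Acapella parameters were means or totals is not stated
anywhere, so the choice is documented here. A cell "has spots" at
`spot_min = 2` or more cytosolic puncta — the screen never defines the
cutoff, so it is configurable and recorded in the configuration hash.
Intensity parameters of wells with fewer than `min_cells = 50` analysed
cells are marked undefined; such wells remain in the table for the
viability gate.

Puncta are found by difference-of-Gaussians blob enhancement at the
spot scale, 8-neighbour local maxima, and a two-part SNR rule: the raw
peak must clear `snr_threshold` (default 5) against the local
median/MAD background, *and* the DoG response must clear the same
ratio against the local DoG noise. The second condition suppresses
single-pixel noise excursions that pass the raw test; both conditions
are monotone in the threshold, so raising it can only remove spots.
`comdet_detect` is the same core parameterised the way the ImageJ
ComDet plugin is quoted (intensity threshold 4, ~4 px particles) with
intensity-weighted subpixel centroids — a semantic re-implementation,
not a claim of bit-compatibility with the plugin.

# Hit calling

Per plate × condition, each parameter is standardised as
`z = (x − median) / (1.4826 · MAD)` with center and scale taken from
the **sample wells** — with thousands of mostly inert genes this is the
standard arrayed-screen choice and is robust to the hits themselves;
NT-referenced and classic mean/SD variants are selectable. A zero MAD
falls back to the SD with a warning. The screen ran triplicate plates
per condition; z-scores are averaged across replicates before calling,
which buffers single-plate artifacts (and is what makes a 3σ effect
reliably exceed |z| = 2: the averaged null has SD 1/√3).

Wells are gated for viability when `z_QC1 ≤ −2` or fewer than 50 cells
were analysed; the PLK1 control must be caught by this gate for a run
to be considered valid. Classification: spots parameters up
(`z_N5` or `z_N9` ≥ z_hit) → *increased intracellular*; additionally
membrane down (`z_N3` ≤ −z_hit) → *altered PM + intracellular*; nuclear
up alone → *increased nuclear*; total signal down alone →
*decreased total*, which is reported but excluded from the hit list
(general loss of NOTCH1 signal); anything else, including
membrane-only changes, is not a hit class. The threshold `z_hit = 2` is
a package default: no z cutoff is published, so the screen's printed
hit totals (231 primary, 73/51 validated) are treated as bookkeeping
inputs, never as quantities this package claims to reproduce from
images. A validation screen confirms a hit only with the same
phenotypic class in the same condition.

# Reporter screen

Luminescence is divided by resazurin fluorescence — the publication
states viability was measured "to account for" proliferation loss
without giving the arithmetic; division is the standard ratiometric
correction and makes the fold change invariant to pure viability
effects (a testable property). Fold changes are taken against the
median of the plate's NT wells (median, not mean, for robustness), so
the NT median fold is exactly 1 by construction. A knockdown modulates
signaling when its fold change moves at least 30% from 1, boundary
inclusive; the EGTA assay window (median stimulated / median
unstimulated NT signal) must reach 2 for a plate pair to be usable.

# Colocalization

`%IntDens = 100 · (ROI IntDens / whole-cell IntDens)`; ROIs are
accepted as masks or polygons (even-odd rasterisation). Spot
colocalization uses greedy one-to-one nearest-neighbour matching in
increasing distance order with a 2 px cap; on instances small enough
for an exhaustive maximum-matching oracle the greedy count agrees in
≥95% of random cases, and the count is symmetric in the channel order
by construction. Replicate summaries enforce the five-ROIs-in-at-least-
five-images rule, boundary inclusive.

# Numerical conventions and degenerate inputs

* 1-based (row, col) pixel indexing throughout, as idiomatic in R;
  spot coordinates are (x = col, y = row).
* Type-7 (linearly interpolated) quantiles everywhere a quantile is
  taken, so LIF values are reproducible to 1e-9 against a sort-and-
  interpolate oracle.
* Empty compartments measure 0 with a warning; blank fields segment to
  zero nuclei; a constant phalloidin channel makes the whole frame one
  cell's foreground.
* Welch t tests with the figure star tiers (ns ≥ 0.05 down to
  **** < 0.0001); two zero-variance samples compare as ns when equal
  and p = 0 when not.
* All randomness is drawn under a locally seeded generator that
  restores the caller's RNG state; identical seeds give byte-identical
  layouts, images and tables.
* Every output table carries a hash of the full configuration, and
  readers can refuse tables written under a different configuration.

# Problem sizes used by the test and acceptance suites

Segmentation recovery runs 20 fields of ~30 cells at 256²; focus QC 50
wells of 8 fields at 160²; hit-calling power uses the statistical twin
at full scale (320 genes × 2 plates × 3 replicates); reporter accuracy
50 seeds × 4 replicate plates; colocalization 20 seeds of 200 planted
spots at 512². These sizes were chosen so the whole suite completes in
minutes on a laptop while leaving the statistical margins comfortable
(e.g. recall and specificity targets are met with slack, not at the
boundary).
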