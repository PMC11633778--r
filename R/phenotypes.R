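#' Knockdown phenotype specification
#'
#' Describes how a gene knockdown redistributes NOTCH1 across compartments
#' and affects viability and reporter signaling. The three compartment
#' fractions give the share of per-cell NOTCH1 signal rendered on the plasma
#' membrane ring, diffusely in the cytosol, and in the nucleus; `spot_rate`
#' is the Poisson mean of intracellular puncta per cell.
#'
#' @param pm_frac,cyto_frac,nuc_frac non-negative fractions of per-cell
#'   NOTCH1 signal on the membrane ring / cytosol / nucleus; must sum to 1.
#' @param spot_rate mean number of intracellular NOTCH1 puncta per cell
#'   (Poisson rate, >= 0).
#' @param cell_count_mult multiplier on expected cells per well (> 0); a
#'   cytotoxic knockdown has a value well below 1.
#' @param signaling_mult multiplier on RBPJ-luciferase reporter activity
#'   (> 0).
#' @param label free-text description of the phenotype class.
#' @return An object of class `phenotype_spec`.
#' @examples
#' phenotype_spec(0.6, 0.3, 0.1, spot_rate = 0.3, label = "NT-like")
#' @export
phenotype_spec <- function(pm_frac, cyto_frac, nuc_frac, spot_rate = 0,
                           cell_count_mult = 1, signaling_mult = 1,
                           label = "") {
  fr <- c(pm_frac, cyto_frac, nuc_frac)
  if (any(fr < 0)) stop("compartment fractions must be >= 0")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("pm_frac + cyto_frac + nuc_frac must sum to 1 (got ",
         format(sum(fr), digits = 12), ")")
  if (spot_rate < 0) stop("spot_rate must be >= 0")
  if (cell_count_mult <= 0 || signaling_mult <= 0)
    stop("multipliers must be > 0")
  structure(list(pm_frac = pm_frac, cyto_frac = cyto_frac,
                 nuc_frac = nuc_frac, spot_rate = spot_rate,
                 cell_count_mult = cell_count_mult,
                 signaling_mult = signaling_mult, label = label),
            class = "phenotype_spec")
}

#' Built-in phenotype presets
#'
#' Canonical phenotype classes used throughout the synthetic screen: the
#' non-targeting baseline (mostly plasma-membrane NOTCH1), an intracellular
#' spots phenotype (endo-lysosomal accumulation), an increased-nuclear
#' phenotype, a cytotoxic transfection control, and a gamma-secretase-like
#' signaling suppressor.
#'
#' @return Named list of [phenotype_spec()] objects: `NT`, `spots`,
#'   `nuclear`, `toxic`, `signaling_off`.
#' @export
phenotype_presets <- function() {
  list(
    NT = phenotype_spec(0.60, 0.30, 0.10, spot_rate = 0.3,
                        label = "NT-like"),
    spots = phenotype_spec(0.30, 0.55, 0.15, spot_rate = 4,
                           label = "increased intracellular spots"),
    nuclear = phenotype_spec(0.35, 0.25, 0.40, spot_rate = 0.3,
                             label = "increased nuclear"),
    toxic = phenotype_spec(0.60, 0.30, 0.10, spot_rate = 0.3,
                           cell_count_mult = 0.1,
                           label = "PLK1-like cytotoxic"),
    signaling_off = phenotype_spec(0.60, 0.30, 0.10, spot_rate = 0.3,
                                   signaling_mult = 0.2,
                                   label = "PSENEN-like suppressor")
  )
}
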