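#' Final concentration after dilution into a well
#'
#' Standard dilution arithmetic used to annotate the screen layout, e.g.
#' adding 10 ul of 12.5 mM EGTA to a 50 ul well gives 2.5 mM, and complexing
#' 20 ul of 50 nM siRNA with 20 ul of cell suspension gives 25 nM.
#'
#' @param stock stock concentration (any unit).
#' @param added_vol volume of stock added.
#' @param final_vol final well volume, same unit as `added_vol`.
#' @return Final concentration in the units of `stock`.
#' @examples
#' final_concentration(12.5, 10, 50) # 2.5 mM EGTA
#' final_concentration(50, 20, 40)   # 25 nM siRNA
#' @export
final_concentration <- function(stock, added_vol, final_vol) {
  stopifnot(added_vol > 0, final_vol > 0)
  if (added_vol > final_vol)
    stop("added_vol (", added_vol, ") exceeds final_vol (", final_vol, ")")
  stock * added_vol / final_vol
}

#' Cells seeded from a suspension
#'
#' @param density cell density (cells per unit volume).
#' @param volume dispensed volume, same volume unit as `density`.
#' @return Expected number of cells seeded.
#' @examples
#' cells_seeded(35, 20) # 700 cells per well
#' @export
cells_seeded <- function(density, volume) {
  stopifnot(density >= 0, volume > 0)
  density * volume
}
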