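#' Unit conventions
#'
#' Diameters are stored in millimetres, pressures in mmHg at the interface
#' (Pascals internally), flows in L/min at the interface (m^3/s internally).
#' Mixed clinical/SI bookkeeping mirrors how the quantities are reported at
#' the bedside versus how the momentum balance is computed.
#'
#' @name vepsim-units
#' @keywords internal
NULL

#  1 mmHg in Pa
PA_PER_MMHG <- 133.322

#  1 L/min in m^3/s
M3S_PER_LMIN <- 1 / 60000

mmHg_to_Pa <- function(p) p * PA_PER_MMHG
Pa_to_mmHg <- function(p) p / PA_PER_MMHG
lmin_to_m3s <- function(q) q * M3S_PER_LMIN
m3s_to_lmin <- function(q) q / M3S_PER_LMIN

#' Cross-sectional area of a circular port
#'
#' @param diameter_mm port diameter in mm; must be positive.
#' @return area in m^2.
#' @examples
#' port_area(12)   # 1.13097e-4 m^2, the caval/pulmonary port
#' port_area(2.5)  # 4.9087e-6 m^2, an aortic nozzle
#' @export
port_area <- function(diameter_mm) {
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0)) {
    stop("port_area(): diameter must be positive and finite", call. = FALSE)
  }
  pi * (diameter_mm / 2000)^2
}
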