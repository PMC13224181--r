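#' @keywords internal
#' @useDynLib oemsol, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Physical constants and the unit system.
##
## All energies are carried internally in kJ/mol and all entropies in
## J/(mol K); molar volumes in L/mol; temperatures in kelvin.  Readers
## accept kcal/mol input and convert on entry.  Every table and fitted
## model carries a unit tag so that coefficients are only compared
## within one unit system.

#' Molar gas constant in kJ/(mol K)
#'
#' R = 8.31446e-3 kJ/(mol K).  Exported as a documented constant because
#' the sublimation-enthalpy offset (-2RT) and the free-energy-to-logS
#' conversion both depend on it.
#'
#' @format A length-one numeric.
#' @export
GAS_CONSTANT_KJ <- 8.31446e-3

#' kJ per kcal (thermochemical calorie)
#' @format A length-one numeric.
#' @export
KJ_PER_KCAL <- 4.184

#' Reference temperature in kelvin
#'
#' Room temperature, 298.15 K; the default wherever a temperature is not
#' supplied.
#' @format A length-one numeric.
#' @export
ROOM_TEMPERATURE_K <- 298.15

.valid_units <- c("kJ", "kcal")

check_unit_system <- function(unit_system) {
  if (!is.character(unit_system) || length(unit_system) != 1L ||
      !unit_system %in% .valid_units) {
    stop("`unit_system` must be one of: ", paste(.valid_units, collapse = ", "),
         call. = FALSE)
  }
  unit_system
}

#' Convert energies into the internal kJ/mol unit system
#'
#' @param x numeric vector of energies.
#' @param from unit system of `x`: `"kJ"` or `"kcal"`.
#' @return `x` expressed in kJ/mol.
#' @export
energy_to_kj <- function(x, from = c("kJ", "kcal")) {
  from <- match.arg(from)
  if (from == "kcal") x * KJ_PER_KCAL else x
}
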