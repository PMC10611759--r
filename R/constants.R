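#' Physical constants used throughout the package
#'
#' Energies are reported in kcal/mol. The gas constant is used at the
#' conventional calorimetric value 1.986 cal/(K mol); Boltzmann and Planck
#' constants are the SI values. `CELSIUS_OFFSET` converts between kelvin and
#' degrees Celsius (37 degrees C = 310.15 K).
#'
#' @format Named numeric constants:
#' \describe{
#'   \item{GAS_CONSTANT_KCAL}{1.986e-3 kcal/(K mol)}
#'   \item{BOLTZMANN_J_PER_K}{1.380649e-23 J/K}
#'   \item{PLANCK_J_S}{6.62607e-34 J s}
#'   \item{CELSIUS_OFFSET}{273.15 K}
#' }
#' @name constants
#' @aliases GAS_CONSTANT_KCAL BOLTZMANN_J_PER_K PLANCK_J_S CELSIUS_OFFSET
NULL

#' @export
GAS_CONSTANT_KCAL <- 1.986e-3

#' @export
BOLTZMANN_J_PER_K <- 1.380649e-23

#' @export
PLANCK_J_S <- 6.62607e-34

#' @export
CELSIUS_OFFSET <- 273.15

# internal helpers
kelvin_to_celsius <- function(K) K - CELSIUS_OFFSET
celsius_to_kelvin <- function(C) C + CELSIUS_OFFSET
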