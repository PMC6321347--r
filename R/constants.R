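#' Physical constants used throughout mechkit
#'
#' All unit conversions in the package go through this single table: CODATA
#' values for Boltzmann's constant, Planck's constant, the gas constant and the
#' speed of light, plus the energy conversion 1 kcal/mol = 349.755 cm^-1.
#'
#' @format A named list:
#' \describe{
#'   \item{kB_J}{Boltzmann constant, J/K}
#'   \item{h_Js}{Planck constant, J s}
#'   \item{R_J}{gas constant, J/(mol K)}
#'   \item{R_kcal}{gas constant, kcal/(mol K)}
#'   \item{c_cm}{speed of light, cm/s}
#'   \item{NA_mol}{Avogadro constant, 1/mol}
#'   \item{kcal_to_cm}{wavenumbers per kcal/mol}
#'   \item{c2_cmK}{second radiation constant h c / kB, cm K}
#' }
#' @export
mech_constants <- list(
  kB_J       = 1.380649e-23,
  h_Js       = 6.62607015e-34,
  R_J        = 8.314462618,
  R_kcal     = 8.314462618 / 4184,
  c_cm       = 2.99792458e10,
  NA_mol     = 6.02214076e23,
  kcal_to_cm = 349.755,
  c2_cmK     = 6.62607015e-34 * 2.99792458e10 / 1.380649e-23
)

# kcal/mol -> cm^-1 and back; pinned here so every module agrees
kcal_to_wavenumber <- function(e_kcal) e_kcal * mech_constants$kcal_to_cm
wavenumber_to_kcal <- function(e_cm) e_cm / mech_constants$kcal_to_cm
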