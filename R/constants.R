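## Physical constants (single source for the whole package).

#' Physical constants used throughout protlink
#'
#' Gas constant in kJ/(mol K), Faraday constant in C/mol and Avogadro's
#' number. All free energies in the package are in kJ/mol unless a
#' kcal/mol conversion is explicitly requested (1 kcal = 4.184 kJ).
#'
#' @format Named numeric vector with elements \code{R_kJ} (8.314462618e-3
#'   kJ/mol/K), \code{faraday} (96485.33212 C/mol), \code{avogadro}
#'   (6.02214076e23 1/mol), \code{kcal_in_kJ} (4.184).
#' @export
protlink_constants <- c(
  R_kJ       = 8.314462618e-3,
  faraday    = 96485.33212,
  avogadro   = 6.02214076e23,
  kcal_in_kJ = 4.184
)

#' RT ln(10) in kJ/mol at temperature T
#'
#' The conversion factor between proton-binding differences and free-energy
#' slopes in the Wyman-Tanford linkage relation
#' \eqn{\partial \Delta G / \partial pH = RT \ln 10\, \Delta n}.
#'
#' @param T Absolute temperature in K (default 300).
#' @return RT ln10 in kJ/mol.
#' @export
RT_ln10 <- function(T = 300) {
  stopifnot(is.numeric(T), T > 0)
  protlink_constants[["R_kJ"]] * T * log(10)
}
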