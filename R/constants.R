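## Unit system: lengths in Angstrom, charges in elementary charges (e),
## energies in kcal/mol, potentials in kcal/mol/e, temperature in Kelvin.

#' Physical constants used throughout the solver
#'
#' @format A list with elements:
#' \describe{
#'   \item{k_coulomb}{Coulomb constant \eqn{e^2/(4\pi\epsilon_0)} in
#'     Angstrom kcal/mol (332.0637).}
#'   \item{k_boltzmann}{Boltzmann constant in kcal/mol/K.}
#'   \item{molar_to_A3}{Conversion from mol/L to particles per cubic
#'     Angstrom (\eqn{N_A \times 10^{-27}}).}
#' }
#' @keywords internal
.pb_constants <- list(
  k_coulomb   = 332.0637,
  k_boltzmann = 0.001987204259,
  molar_to_A3 = 6.02214076e-4
)

#' Thermal energy kT in kcal/mol
#' @param temperature temperature in Kelvin
#' @return kT in kcal/mol
#' @keywords internal
.kT <- function(temperature) .pb_constants$k_boltzmann * temperature

#' Inverse Debye length
#'
#' \eqn{\kappa^2 = 8\pi k_e \beta N_A I_s / \epsilon_s} with the ionic
#' strength \eqn{I_s = \frac12 \sum c_{bi} z_i^2} in mol/L.
#'
#' @param ionic_strength mol/L
#' @param eps_s solvent relative dielectric
#' @param temperature Kelvin
#' @return kappa in 1/Angstrom
#' @export
#' @examples
#' debye_kappa(0.05, 80)  # ~0.073 1/A, i.e. a ~13.7 A Debye length
debye_kappa <- function(ionic_strength, eps_s, temperature = 298.15) {
  stopifnot(ionic_strength >= 0, eps_s >= 1)
  beta <- 1 / .kT(temperature)
  sqrt(8 * pi * .pb_constants$k_coulomb * beta *
         .pb_constants$molar_to_A3 * ionic_strength / eps_s)
}
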