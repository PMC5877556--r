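## Physical parameter containers: dielectric constants per region, mobile
## ion species, temperature, and derived quantities (beta, ionic strength,
## Debye kappa).

#' Physics parameters for a Poisson-Boltzmann solve
#'
#' @param eps_m solute relative dielectric (default 2)
#' @param eps_s solvent relative dielectric (default 80)
#' @param eps_mem membrane relative dielectric (default 2)
#' @param species data frame with columns `z` (valence) and `molar`
#'   (bulk concentration, mol/L); NULL or zero rows means no mobile ions
#' @param temperature Kelvin (default 298.15)
#' @return an object of class `pb_params` with derived fields `beta`
#'   (1/kcal/mol), `ionic_strength` (mol/L) and `kappa` (1/Angstrom)
#' @export
#' @examples
#' physics_params(species = salt_species(0.05))
physics_params <- function(eps_m = 2, eps_s = 80, eps_mem = 2,
                           species = NULL, temperature = 298.15) {
  stopifnot(eps_m >= 1, eps_s >= 1, eps_mem >= 1, temperature > 0)
  if (is.null(species))
    species <- data.frame(z = numeric(0), molar = numeric(0))
  stopifnot(is.data.frame(species), all(c("z", "molar") %in% names(species)),
            all(species$molar >= 0))
  Is <- if (nrow(species)) sum(species$molar * species$z^2) / 2 else 0
  structure(list(eps_m = eps_m, eps_s = eps_s, eps_mem = eps_mem,
                 species = species, temperature = temperature,
                 beta = 1 / .kT(temperature),
                 ionic_strength = Is,
                 kappa = debye_kappa(Is, eps_s, temperature)),
            class = "pb_params")
}

#' Symmetric 1:1 salt species table
#' @param molar bulk salt concentration (mol/L)
#' @return data frame usable as the `species` argument of [physics_params()]
#' @export
salt_species <- function(molar) {
  if (molar == 0) return(NULL)
  data.frame(z = c(1, -1), molar = c(molar, molar))
}

#' @export
print.pb_params <- function(x, ...) {
  cat(sprintf("pb_params: eps_m=%g eps_s=%g eps_mem=%g T=%g K\n",
              x$eps_m, x$eps_s, x$eps_mem, x$temperature))
  cat(sprintf("  ionic strength %g M, kappa %g 1/A\n",
              x$ionic_strength, x$kappa))
  invisible(x)
}

.check_electroneutral <- function(params) {
  sp <- params$species
  if (nrow(sp) && abs(sum(sp$z * sp$molar)) > 1e-12 * sum(abs(sp$molar)))
    stop("ion species set is not electroneutral (sum z_i c_i != 0)")
}

#' Newton iteration settings for the nonlinear PB solve
#'
#' @param max_iter maximum Newton iterations
#' @param residual_tol relative nonlinear residual tolerance
#' @param relaxation initial damping factor in (0, 1]; doubled towards 1 on
#'   residual decrease, halved on increase
#' @param linear_tol relative tolerance of each inner linear solve
#' @return an object of class `newton_config`
#' @export
newton_config <- function(max_iter = 50, residual_tol = 1e-9,
                          relaxation = 0.5, linear_tol = 1e-10) {
  stopifnot(relaxation > 0, relaxation <= 1, max_iter >= 1)
  structure(list(max_iter = max_iter, residual_tol = residual_tol,
                 relaxation = relaxation, linear_tol = linear_tol),
            class = "newton_config")
}
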