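## Electrostatic, non-polar and total solvation energies, the analytic
## Born oracle and the relative-error metric.

#' Analytic Born solvation energy of a single spherical ion
#'
#' \deqn{\Delta G_{ele} = \frac{k_e q^2}{2 r}\left(\frac{1}{\epsilon_s} -
#'   \frac{1}{\epsilon_m}\right)}
#' negative (favourable) for \eqn{\epsilon_s > \epsilon_m}. With q = 1 e,
#' r = 1 Angstrom, \eqn{\epsilon_m = 2}, \eqn{\epsilon_s = 80} this gives
#' -80.94 kcal/mol.
#'
#' @param q charge (e)
#' @param r ion radius (Angstrom)
#' @param eps_m,eps_s interior/exterior relative dielectrics
#' @return energy in kcal/mol
#' @export
born_analytic <- function(q = 1, r = 1, eps_m = 2, eps_s = 80) {
  stopifnot(r > 0, eps_m >= 1, eps_s >= 1)
  .pb_constants$k_coulomb * q^2 / (2 * r) * (1 / eps_s - 1 / eps_m)
}

#' Relative error of a numerical solvation energy, in percent
#' @param exact reference value
#' @param numeric_value computed value
#' @return `|exact - numeric| / |exact| * 100`
#' @export
relative_error_pct <- function(exact, numeric_value)
  abs((exact - numeric_value) / exact) * 100

#' Electrostatic solvation energy from two solutions
#'
#' \eqn{\Delta G_{ele} = \frac12 \sum_i q_i (\phi_{i,sys} - \phi_{i,ref})}
#' using the per-atom potentials interpolated identically in both states.
#' Both solutions must come from the same mesh so the singular numerical
#' error at the charges cancels in the difference.
#'
#' @param mol a `pb_molecule`
#' @param sol_sys solvated-state `pb_solution`
#' @param sol_ref reference-state `pb_solution`
#' @return energy in kcal/mol
#' @export
electrostatic_energy <- function(mol, sol_sys, sol_ref) {
  if (!isTRUE(all.equal(sol_sys$mesh_sig, sol_ref$mesh_sig)))
    stop("solvated and reference solutions are not on the same mesh")
  0.5 * sum(mol$charges * (sol_sys$phi_atoms - sol_ref$phi_atoms))
}

#' Electrostatic energy of a continuous charge density
#'
#' For loads that represent a continuous source (e.g. the uniform-ball
#' charge model), \eqn{\Delta G = \frac12 \int \rho (\phi_{sys} -
#' \phi_{ref}) = \frac12 \sum_j b_j (\phi_{sys,j} - \phi_{ref,j})} with
#' `load` the per-vertex weak-form load in e units.
#'
#' @param load per-vertex load (e)
#' @param sol_sys,sol_ref `pb_solution`s on the same mesh
#' @param params a `pb_params` (for the u -> kcal/mol/e conversion)
#' @return energy in kcal/mol
#' @export
electrostatic_energy_density <- function(load, sol_sys, sol_ref, params) {
  if (!isTRUE(all.equal(sol_sys$mesh_sig, sol_ref$mesh_sig)))
    stop("solutions are not on the same mesh")
  0.5 * sum(load * (sol_sys$u - sol_ref$u)) / params$beta
}

#' Solve both states and report the electrostatic solvation energy
#'
#' The standard two-solve protocol: the solvated state (region
#' dielectrics, mobile ions on) and the reference state (uniform solute
#' dielectric, no ions) are solved on the identical mesh with the
#' identical fixed-charge load, and the energy is the half-sum of charge
#' times per-atom potential difference.
#'
#' @inheritParams solve_state
#' @param charge_method one of `"direct"`, `"vertex"`, `"average"`,
#'   `"weighted"` (see [charge_load()])
#' @param r_cut truncation radius for the average method
#' @return list with `dG_ele` (kcal/mol), `sol_sys`, `sol_ref`, `load`
#' @export
electrostatic_solvation <- function(mesh, mol, params,
                                    charge_method = "direct",
                                    bc_mode = "dirichlet", pmap = NULL,
                                    cfg = newton_config(), r_cut = 1.0) {
  load <- charge_load(mol, mesh, charge_method, r_cut)
  if (bc_mode == "periodic" && is.null(pmap))
    pmap <- build_periodic_map(mesh)
  sol_sys <- solve_state(mesh, mol, load, params, "SOLVATED", bc_mode,
                         pmap, cfg, ionic = "auto")
  sol_ref <- solve_state(mesh, mol, load, params, "REFERENCE", bc_mode,
                         pmap, cfg, ionic = "off")
  list(dG_ele = electrostatic_energy(mol, sol_sys, sol_ref),
       sol_sys = sol_sys, sol_ref = sol_ref, load = load)
}

## ---- non-polar term -----------------------------------------------------

#' Depth-dependent surface tension profile S(z)
#'
#' Piecewise-linear profile for the membrane environment: S = 1 in bulk
#' water, `s_core` inside the slab `[z1, z2]`, with linear ramps of width
#' `w` outside each slab face.
#'
#' @param z1,z2 membrane slab faces (Angstrom)
#' @param s_core relative surface tension inside the slab (default 0)
#' @param w ramp width (Angstrom, default 3)
#' @param gamma surface tension in kcal/mol per square Angstrom
#' @return an object of class `tension_profile`; call it on z values
#' @export
surface_tension_profile <- function(z1 = -15, z2 = 15, s_core = 0, w = 3,
                                    gamma = 0.005) {
  stopifnot(z1 < z2, w >= 0, s_core >= 0)
  f <- function(z) {
    s <- rep(1, length(z))
    inside <- z >= z1 & z <= z2
    s[inside] <- s_core
    if (w > 0) {
      lo <- z > z1 - w & z < z1
      s[lo] <- 1 + (s_core - 1) * (z[lo] - (z1 - w)) / w
      hi <- z > z2 & z < z2 + w
      s[hi] <- s_core + (1 - s_core) * (z[hi] - z2) / w
    }
    s
  }
  structure(list(S = f, gamma = gamma, z1 = z1, z2 = z2,
                 s_core = s_core, w = w),
            class = "tension_profile")
}

#' Non-polar solvation energy
#'
#' \eqn{\Delta G_{np} = \gamma \sum_i S(z_i) SA_i} with the per-atom
#' solvent-accessible areas and the membrane-depth-dependent tension
#' profile.
#'
#' @param mol a `pb_molecule`
#' @param sasa per-atom areas from [compute_sasa()] (same atom order)
#' @param profile a [surface_tension_profile()]
#' @return energy in kcal/mol
#' @export
nonpolar_energy <- function(mol, sasa, profile) {
  if (length(sasa) != nrow(mol$positions))
    stop("sasa length does not match the number of atoms")
  profile$gamma * sum(profile$S(mol$positions[, 3]) * sasa)
}

#' Total solvation energy report
#' @param dG_ele,dG_np electrostatic and non-polar parts (kcal/mol)
#' @return list with `dG_ele`, `dG_np` and their exact sum `dG_sol`
#' @export
energy_report <- function(dG_ele, dG_np)
  list(dG_ele = dG_ele, dG_np = dG_np, dG_sol = dG_ele + dG_np)
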