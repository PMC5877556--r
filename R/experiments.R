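## Desk-scale experiment drivers: Born refinement/error studies, box-size
## sweeps comparing boundary conditions and solution methods, membrane
## dielectric/thickness sweeps, the wrongly-filled-pore (HMP) control, and
## the tilt-angle scan.

#' Uniform-ball charge load (continuous single-atom model)
#'
#' Spreads a total charge `q` uniformly over the SOLUTE region (the unit
#' ball in the Born fixture) as a continuous density. The exact solvation
#' energy of this model equals the point-charge Born value, but the source
#' is regular, so refinement converges monotonically.
#'
#' @param mesh a `pb_mesh` whose SOLUTE region is the charged ball
#' @param q total charge (e)
#' @return per-vertex load vector (e)
#' @export
uniform_ball_load <- function(mesh, q = 1) {
  sol <- mesh$region == "SOLUTE"
  vol <- tet_volumes(mesh)
  rho <- q / sum(vol[sol])
  b <- numeric(nrow(mesh$vertices))
  st <- mesh$tets[sol, , drop = FALSE]
  for (k in 1:4) {
    s <- rowsum(rho * vol[sol] / 4, st[, k])
    ids <- as.integer(rownames(s))
    b[ids] <- b[ids] + s[, 1]
  }
  b
}

#' Born single-ion refinement study
#'
#' Solves the classic Born model (unit charge at the centre of a unit
#' dielectric sphere in a large solvent sphere) on a graded mesh and a
#' sequence of uniform refinements, and reports the relative error of the
#' FEM solvation energy against the analytic value at each level.
#'
#' @param spec a [born_spec()]
#' @param params a `pb_params` (no ions for the classic model)
#' @param levels number of refinement levels including the coarse mesh
#' @param charge_method fixed-charge treatment (see [charge_load()])
#' @param source `"point"` for the singular charge at the centre vertex,
#'   `"uniform"` for the uniform-ball continuous charge model
#' @param q central charge (e)
#' @param r_cut truncation radius for the average method
#' @param project `"radial"` re-projects new vertices onto the concentric
#'   shells during refinement, so the faceted spheres converge to the true
#'   geometry; `"none"` is plain midpoint refinement, which keeps the
#'   coarse polyhedral dielectric interface fixed - the behaviour of
#'   uniform refinement of a body-fitted mesh whose surface was
#'   triangulated once
#' @return data frame with columns `level`, `elements`, `dofs`,
#'   `edge_equiv` (equivalent edge length within 5 Angstrom of the
#'   centre), `dG_ele`, `error_pct`
#' @export
born_study <- function(spec = born_spec(), params = physics_params(),
                       levels = 2, charge_method = "direct",
                       source = c("point", "uniform"), q = 1,
                       r_cut = 1.0, project = c("radial", "none")) {
  source <- match.arg(source)
  project <- match.arg(project)
  exact <- born_analytic(q, spec$r_in, params$eps_m, params$eps_s)
  mol <- molecule(matrix(0, 1, 3), q, spec$r_in)
  mesh <- make_born_mesh(spec)
  proj <- if (project == "radial") radial_projection(c(0, 0, 0)) else NULL
  out <- vector("list", levels)
  for (lev in seq_len(levels)) {
    if (lev > 1) mesh <- refine_uniform(mesh, project = proj)
    if (source == "point") {
      res <- electrostatic_solvation(mesh, mol, params, charge_method,
                                     r_cut = r_cut)
      dg <- res$dG_ele
    } else {
      load <- uniform_ball_load(mesh, q)
      ss <- solve_state(mesh, mol, load, params, "SOLVATED")
      sr <- solve_state(mesh, mol, load, params, "REFERENCE", ionic = "off")
      dg <- electrostatic_energy_density(load, ss, sr, params)
    }
    out[[lev]] <- data.frame(
      level = lev - 1L, elements = nrow(mesh$tets),
      dofs = nrow(mesh$vertices),
      edge_equiv = equivalent_edge_length(mesh, c(0, 0, 0), 5),
      dG_ele = dg, error_pct = relative_error_pct(exact, dg))
  }
  do.call(rbind, out)
}

#' Box-size sweep: periodic vs Dirichlet vs decomposition
#'
#' For a fixed molecule and a sequence of cubic box sizes, computes the
#' electrostatic solvation energy with (a) lateral periodic boundary
#' conditions, (b) plain Dirichlet boundaries, and (c) the decomposition
#' method under Dirichlet boundaries. As the box grows the periodic and
#' non-periodic energies converge.
#'
#' @param mol a `pb_molecule` centred in the box
#' @param box_sizes cubic box edge lengths (Angstrom)
#' @param h target cube edge of the structured mesh (Angstrom)
#' @param params a `pb_params`
#' @param margin solute labelling margin (Angstrom), see [label_solute()];
#'   a fixed physical cavity parameter, which must exceed the mesh tet
#'   diameter so every atom lies strictly inside a SOLUTE tet
#' @return data frame with columns `box`, `dG_periodic`, `dG_dirichlet`,
#'   `dG_decomposed`
#' @export
box_sweep <- function(mol, box_sizes = c(40, 60, 80, 100), h = 2.5,
                      params = physics_params(species = salt_species(0.05)),
                      margin = 6) {
  out <- vector("list", length(box_sizes))
  for (i in seq_along(box_sizes)) {
    L <- box_sizes[i]
    n <- max(4L, round(L / h))
    mesh <- make_box_mesh(rep(-L / 2, 3), rep(L / 2, 3), rep(n, 3))
    mesh <- label_solute(mesh, mol, margin = margin, periodic = TRUE)
    per <- electrostatic_solvation(mesh, mol, params, bc_mode = "periodic")
    dir <- electrostatic_solvation(mesh, mol, params, bc_mode = "dirichlet")
    dec <- solve_decomposed(mesh, mol, params)
    out[[i]] <- data.frame(box = L, dG_periodic = per$dG_ele,
                           dG_dirichlet = dir$dG_ele,
                           dG_decomposed = dec$energy)
  }
  do.call(rbind, out)
}

## build a labelled channel mesh: slab + pore recognition
.channel_labelled <- function(sys, mspec) {
  mesh <- label_membrane(sys$mesh, mspec)
  pore <- detect_pore(mesh, mspec, seed = "auto")
  list(mesh = apply_pore(mesh, pore), pore = pore)
}

#' Membrane dielectric sweep on a channel system
#'
#' @param sys a channel system from [make_channel_system()]
#' @param eps_mem_values membrane dielectric constants to scan
#' @param ionic_strengths 1:1 salt concentrations (mol/L) to scan
#' @param z1,z2 membrane slab faces
#' @param bc_mode boundary-condition mode
#' @return data frame with `eps_mem`, `ionic_strength`, `dG_ele`
#' @export
membrane_sweep <- function(sys, eps_mem_values = c(1, 2, 4, 8),
                           ionic_strengths = c(0, 0.05),
                           z1 = -15, z2 = 15, bc_mode = "periodic") {
  lab <- .channel_labelled(sys, membrane_spec(z1, z2))
  pmap <- if (bc_mode == "periodic") build_periodic_map(lab$mesh) else NULL
  out <- list()
  for (Is in ionic_strengths) for (em in eps_mem_values) {
    params <- physics_params(eps_mem = em, species = salt_species(Is))
    res <- electrostatic_solvation(lab$mesh, sys$mol, params,
                                   bc_mode = bc_mode, pmap = pmap)
    out[[length(out) + 1L]] <- data.frame(
      eps_mem = em, ionic_strength = Is, dG_ele = res$dG_ele)
  }
  do.call(rbind, out)
}

#' Membrane thickness sweep on a channel system
#'
#' Slabs are centred at z = 0 with the given thicknesses.
#'
#' @inheritParams membrane_sweep
#' @param thicknesses slab thicknesses (Angstrom)
#' @param eps_mem membrane dielectric
#' @return data frame with `thickness`, `dG_ele`
#' @export
thickness_sweep <- function(sys, thicknesses = c(10, 20, 30), eps_mem = 1,
                            ionic_strength = 0.05, bc_mode = "periodic") {
  out <- list()
  for (th in thicknesses) {
    lab <- .channel_labelled(sys, membrane_spec(-th / 2, th / 2))
    params <- physics_params(eps_mem = eps_mem,
                            species = salt_species(ionic_strength))
    res <- electrostatic_solvation(lab$mesh, sys$mol, params,
                                   bc_mode = bc_mode)
    out[[length(out) + 1L]] <- data.frame(thickness = th, dG_ele = res$dG_ele)
  }
  do.call(rbind, out)
}

#' Wrongly-filled-pore (HMP) control experiment
#'
#' Quantifies the cost of failing to recognise the channel: a central band
#' of the pore of height `hmp` is incorrectly labelled membrane, and the
#' electrostatic solvation energy is tracked as the band shrinks to zero.
#'
#' @inheritParams membrane_sweep
#' @param hmp_values heights of membrane-in-pore (Angstrom)
#' @param eps_mem membrane dielectric
#' @return data frame with `hmp`, `dG_ele`
#' @export
hmp_study <- function(sys, hmp_values = c(30, 20, 10, 0), eps_mem = 2,
                      ionic_strength = 0.05, z1 = -15, z2 = 15,
                      bc_mode = "periodic") {
  mspec <- membrane_spec(z1, z2, eps_mem)
  lab <- .channel_labelled(sys, mspec)
  pmap <- if (bc_mode == "periodic") build_periodic_map(lab$mesh) else NULL
  params <- physics_params(eps_mem = eps_mem,
                           species = salt_species(ionic_strength))
  out <- list()
  for (hmp in hmp_values) {
    mesh_h <- fill_pore_partial(lab$mesh, lab$pore, mspec, hmp)
    res <- electrostatic_solvation(mesh_h, sys$mol, params,
                                   bc_mode = bc_mode, pmap = pmap)
    out[[length(out) + 1L]] <- data.frame(hmp = hmp, dG_ele = res$dG_ele)
  }
  do.call(rbind, out)
}

#' Tilt-angle scan of the total solvation energy
#'
#' Rotates the molecule about an in-plane axis, rebuilds/relabels the mesh
#' through `mesh_builder`, solves both states and adds the non-polar term;
#' the scan minimum estimates the preferred tilt of a membrane channel.
#'
#' @param mol a `pb_molecule`
#' @param mesh_builder function(mol) returning a labelled `pb_mesh` ready
#'   to solve (slab inserted, pore recognised)
#' @param angles tilt angles in degrees
#' @param params a `pb_params`
#' @param profile a [surface_tension_profile()]
#' @param axis in-plane rotation axis
#' @param bc_mode boundary-condition mode
#' @return data frame with `angle`, `dG_ele`, `dG_np`, `dG_sol`; the
#'   attribute `argmin` holds the angle of minimal total energy
#' @export
tilt_scan <- function(mol, mesh_builder, angles, params, profile,
                      axis = c(1, 0, 0), bc_mode = "dirichlet") {
  out <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    molr <- rotate_molecule(mol, angles[i], axis)
    mesh <- mesh_builder(molr)
    ele <- electrostatic_solvation(mesh, molr, params, bc_mode = bc_mode)
    np <- nonpolar_energy(molr, compute_sasa(molr), profile)
    rep_ <- energy_report(ele$dG_ele, np)
    out[[i]] <- data.frame(angle = angles[i], dG_ele = rep_$dG_ele,
                           dG_np = rep_$dG_np, dG_sol = rep_$dG_sol)
  }
  res <- do.call(rbind, out)
  attr(res, "argmin") <- res$angle[which.min(res$dG_sol)]
  res
}
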