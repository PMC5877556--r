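test_that("unit right tet stiffness equals the hand-integrated matrix", {
  m <- unit_right_tet()
  A <- as.matrix(assemble_stiffness(m, 1))
  # grad l1 = (-1,-1,-1), grad l2 = e1, grad l3 = e2, grad l4 = e3; V = 1/6
  K <- rbind(c(3, -1, -1, -1), c(-1, 1, 0, 0),
             c(-1, 0, 1, 0), c(-1, 0, 0, 1)) / 6
  expect_equal(A, K, tolerance = 1e-14)
  expect_equal(as.matrix(assemble_stiffness(m, 2)), 2 * K, tolerance = 1e-14)
})

test_that("assembled stiffness is symmetric with zero row sums, PSD", {
  m <- small_born_mesh()
  A <- assemble_stiffness(m, c(SOLUTE = 2, SOLVENT = 80, MEMBRANE = 2))
  expect_lt(max(abs(A - Matrix::t(A))), 1e-9)
  expect_lt(max(abs(Matrix::rowSums(A))), 1e-9)
  set.seed(1)
  for (k in 1:5) {
    x <- rnorm(nrow(A))
    expect_gte(as.numeric(x %*% (A %*% x)), -1e-9)
  }
})

test_that("Dirichlet values follow the screened-Coulomb closed form", {
  params <- physics_params(species = salt_species(0.05))
  mol0 <- molecule(matrix(0, 1, 3), 0, 1)
  pts <- matrix(rnorm(30), ncol = 3) * 5 + 10
  expect_equal(dirichlet_values(mol0, params, pts), rep(0, 10))
  mol <- molecule(matrix(0, 1, 3), 1, 1)
  p0 <- physics_params()                          # no ions: kappa = 0
  ke_beta <- 332.0637 / (0.001987204259 * 298.15)
  for (d in c(5, 10, 20)) {
    u <- dirichlet_values(mol, p0, matrix(c(d, 0, 0), 1))
    expect_equal(u, ke_beta / (80 * d), tolerance = 1e-6)
  }
  # doubling the distance halves the unscreened value
  u1 <- dirichlet_values(mol, p0, matrix(c(7, 0, 0), 1))
  u2 <- dirichlet_values(mol, p0, matrix(c(14, 0, 0), 1))
  expect_equal(u1 / u2, 2, tolerance = 1e-12)
  # screening multiplies by exp(-kappa d)
  for (d in c(6, 13, 21)) {
    us <- dirichlet_values(mol, params, matrix(c(0, d, 0), 1))
    u0 <- dirichlet_values(mol, p0, matrix(c(0, d, 0), 1))
    expect_equal(us / u0, exp(-params$kappa * d), tolerance = 1e-12)
  }
  # reference state uses the solute dielectric and no screening
  ur <- dirichlet_values(mol, params, matrix(c(9, 0, 0), 1), "REFERENCE")
  expect_equal(ur, ke_beta / (2 * 9), tolerance = 1e-6)
  expect_error(dirichlet_values(mol, p0, matrix(0, 1, 3)), "coincides")
})

test_that("linear solve: zero load gives zero, doubling charges doubles u", {
  m <- small_born_mesh()
  params <- physics_params()
  mol0 <- molecule(matrix(0, 1, 3), 0, 1)
  s0 <- solve_linear(m, mol0, numeric(nrow(m$vertices)), params)
  expect_equal(max(abs(s0$u)), 0)
  mol1 <- molecule(matrix(0, 1, 3), 1, 1)
  mol2 <- molecule(matrix(0, 1, 3), 2, 1)
  u1 <- solve_linear(m, mol1, direct_load(mol1, m), params)$u
  u2 <- solve_linear(m, mol2, direct_load(mol2, m), params)$u
  expect_equal(u2, 2 * u1, tolerance = 1e-9)
})

test_that("zero fixed charge in symmetric salt solves to u = 0", {
  mesh <- label_solute(make_box_mesh(rep(-10, 3), rep(10, 3), rep(6, 3)),
                       molecule(matrix(0, 1, 3), 0, 2), margin = 5)
  mol <- molecule(matrix(0, 1, 3), 0, 2)
  params <- physics_params(species = salt_species(0.1))
  sol <- solve_pb_newton(mesh, mol, numeric(nrow(mesh$vertices)), params)
  expect_lt(max(abs(sol$u)), 1e-12)
})

test_that("non-electroneutral species sets are rejected for the PB solve", {
  mesh <- label_solute(make_box_mesh(rep(-10, 3), rep(10, 3), rep(6, 3)),
                       molecule(matrix(0, 1, 3), 1, 2), margin = 5)
  mol <- molecule(matrix(0, 1, 3), 1, 2)
  bad <- physics_params(species = data.frame(z = 1, molar = 0.1))
  expect_error(
    solve_pb_newton(mesh, mol, direct_load(mol, mesh), bad),
    "electroneutral")
})

test_that("small-charge PB matches the linearized operator at cubic order", {
  mesh <- label_solute(make_box_mesh(rep(-15, 3), rep(15, 3), rep(10, 3)),
                       molecule(matrix(0, 1, 3), 0, 3), margin = 5.5)
  params <- physics_params(species = salt_species(0.1))
  base <- make_random_cluster(5, total_charge = 0.002, radius = 2, seed = 2)
  run <- function(s) {
    mol <- molecule(base$positions, base$charges * s, base$radii)
    load <- charge_load(mol, mesh, "direct")
    unl <- solve_pb_newton(mesh, mol, load, params)$u
    uln <- solve_linearized(mesh, mol, load, params)$u
    c(dev = max(abs(unl - uln)), scale = max(abs(unl)))
  }
  r1 <- run(1); r2 <- run(0.5)
  # first-order agreement: deviation is a tiny fraction of the solution
  expect_lt(r1["dev"] / r1["scale"], 1e-4)
  # remainder shrinks cubically with the charge
  expect_equal(unname(r1["dev"] / r2["dev"]), 8, tolerance = 0.15)
  # at milli-e charges the two solvers coincide to solver precision
  r3 <- run(1e-3)
  expect_lt(r3["dev"] / max(r3["scale"], 1e-12), 1e-6)
})

test_that("periodic-mode systems remain symmetric and solvable", {
  mol <- make_random_cluster(6, total_charge = -2, radius = 3, seed = 12)
  mesh <- label_solute(make_box_mesh(rep(-12, 3), rep(12, 3), rep(8, 3)),
                       mol, margin = 6, periodic = TRUE)
  params <- physics_params(species = salt_species(0.05))
  res <- electrostatic_solvation(mesh, mol, params, bc_mode = "periodic")
  expect_true(is.finite(res$dG_ele))
  expect_lt(res$dG_ele, 0)
  # solvated and reference potentials are finite everywhere
  expect_true(all(is.finite(res$sol_sys$u)))
  expect_true(all(is.finite(res$sol_ref$u)))
})
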