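test_that("PQR parsing takes the last five numeric fields, in file order", {
  d <- withr::local_tempdir()
  p <- file.path(d, "m.pqr")
  writeLines(c(
    "REMARK   synthetic two-atom fixture",
    "ATOM      1  N   ALA A   1      0.000   0.000   0.000  0.5000 1.5000",
    "ATOM      2  O   ALA     2      1.000   2.000   3.000 -0.5000 1.2000",
    "TER", "END"), p)
  mol <- read_pqr(p)
  expect_equal(nrow(mol$positions), 2L)
  expect_equal(net_charge(mol), 0)
  expect_equal(mol$positions[2, ], c(1, 2, 3))
  expect_equal(mol$radii, c(1.5, 1.2))

  writeLines(c("ATOM 1 X UNK 1 0 0 0 1.0 1.0"), p)
  expect_equal(net_charge(read_pqr(p)), 1)
  writeLines(c("ATOM 1 X UNK 1 0 0 0 q r"), p)
  expect_error(read_pqr(p), "line 1")
})

test_that("PQR round trip and the DNA-like 778-atom fixture shape", {
  d <- withr::local_tempdir()
  mol <- make_random_cluster(778, total_charge = -22, radius = 12, seed = 5)
  expect_equal(net_charge(mol), -22)
  p <- write_pqr(mol, file.path(d, "dna.pqr"))
  mol2 <- read_pqr(p)
  expect_equal(net_charge(mol2), -22, tolerance = 1e-6)
  expect_equal(nrow(mol2$positions), 778L)
  expect_equal(mol2$positions, mol$positions, tolerance = 1e-3)
})

test_that("isolated-atom SASA matches the closed form", {
  mol <- molecule(matrix(0, 1, 3), 1, 1)
  expect_equal(compute_sasa(mol, probe = 1.4), 4 * pi * 2.4^2,
               tolerance = 1e-12)
  # two far-apart atoms are both fully exposed
  mol2 <- molecule(rbind(c(0, 0, 0), c(100, 0, 0)), c(1, 1), c(1, 1))
  expect_equal(compute_sasa(mol2, probe = 1.4),
               rep(4 * pi * 2.4^2, 2), tolerance = 1e-12)
})

test_that("two-sphere SASA matches the spherical-cap overlap formula", {
  r <- 1.5; probe <- 1.4; R <- r + probe
  for (dist in c(1.0, 2.5, 4.0, 5.5)) {
    mol <- molecule(rbind(c(0, 0, 0), c(dist, 0, 0)), c(0, 0), c(r, r))
    got <- compute_sasa(mol, probe = probe, n_points = 960)
    h <- R - dist / 2                       # buried cap height (equal radii)
    analytic <- 4 * pi * R^2 - 2 * pi * R * h
    err_bound <- 3 * (4 * pi * R^2) / 960   # point-sampling resolution
    expect_lt(abs(got[1] - analytic), err_bound)
    # mirror symmetry up to point-sampling noise
    expect_equal(got[1], got[2], tolerance = 0.01)
  }
})

test_that("SASA is bounded, non-negative and rigid-motion invariant", {
  mol <- make_random_cluster(12, 0, radius = 3, seed = 9)
  a0 <- compute_sasa(mol)
  expect_true(all(a0 >= 0))
  expect_true(all(a0 <= 4 * pi * (mol$radii + 1.4)^2 + 1e-9))
  molr <- rotate_molecule(shift_molecule(mol, c(3, -2, 7)), 35, c(1, 1, 0))
  a1 <- compute_sasa(molr)
  expect_equal(a1, a0, tolerance = 0.02)
})

test_that("rotation is an isometry about the centroid, in-plane axis only", {
  mol <- make_random_cluster(10, 2, radius = 4, seed = 4)
  expect_equal(rotate_molecule(mol, 0)$positions, mol$positions,
               tolerance = 1e-14)
  expect_equal(rotate_molecule(mol, 360)$positions, mol$positions,
               tolerance = 1e-12)
  molr <- rotate_molecule(mol, 73.2, c(2, 1, 0))
  d0 <- dist(mol$positions); d1 <- dist(molr$positions)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-12)
  expect_identical(molr$charges, mol$charges)
  expect_error(rotate_molecule(mol, 10, c(0, 0, 1)), "membrane")
})

test_that("lattice wraparound keeps positions inside the box", {
  box <- list(lower = c(-10, -10, -10), upper = c(10, 10, 10))
  mol <- molecule(matrix(c(8, 0, 5), 1, 3), 1, 1)
  m2 <- shift_molecule(mol, c(20, 0, 0), box)
  expect_equal(m2$positions[1, ], c(8, 0, 5))     # full lattice vector
  m3 <- shift_molecule(mol, c(5, 0, 0), box)
  expect_equal(m3$positions[1, 1], -7)            # re-enters opposite face
  m4 <- shift_molecule(mol, c(0, 0, 30), box)     # z is not wrapped
  expect_equal(m4$positions[1, 3], 35)
})
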