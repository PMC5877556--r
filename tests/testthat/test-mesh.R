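test_that("construction enforces orientation and rejects bad input", {
  m <- regular_tet_mesh()
  expect_gt(tet_volumes(m), 0)
  # deliberately inverted ordering gets fixed
  v <- m$vertices
  m2 <- tet_mesh(v, matrix(c(1, 2, 4, 3), 1), "SOLUTE")
  expect_gt(tet_volumes(m2), 0)
  expect_error(tet_mesh(v, matrix(c(1, 2, 3, 5), 1), "SOLUTE"),
               "out of range")
  expect_error(tet_mesh(v, matrix(1:4, 1), "WATER"), "unknown region")
  # zero-volume tet
  vz <- rbind(v[1:3, ], v[1, ])
  expect_error(tet_mesh(vz, matrix(1:4, 1), "SOLUTE"), "degenerate")
})

test_that("octasection produces 8 children, 10 vertices, conforming faces", {
  m <- regular_tet_mesh()
  m$boundary_faces <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  m$boundary_marker <- rep("OUTER", 4)
  r <- refine_uniform(m)
  expect_equal(nrow(r$tets), 8L)
  expect_equal(nrow(r$vertices), 10L)
  expect_equal(nrow(r$boundary_faces), 16L)   # boundary faces quadruple
  expect_true(all(tet_volumes(r) > 0))
  expect_equal(sum(tet_volumes(r)), sum(tet_volumes(m)), tolerance = 1e-14)
  adj <- face_adjacency(r)
  expect_equal(adj$n_boundary_faces, 16L)
})

test_that("refinement conserves per-region volume and scales counts by 8", {
  m <- small_born_mesh()
  r <- refine_uniform(m)
  expect_equal(nrow(r$tets), 8L * nrow(m$tets))
  expect_equal(nrow(r$boundary_faces), 4L * nrow(m$boundary_faces))
  for (reg in c("SOLUTE", "SOLVENT")) {
    v0 <- sum(tet_volumes(m)[m$region == reg])
    v1 <- sum(tet_volumes(r)[r$region == reg])
    expect_equal(v1, v0, tolerance = 1e-12)
  }
  expect_true(all(tet_volumes(r) > 0))
})

test_that("radial projection keeps refined shells on their spheres", {
  m <- small_born_mesh()
  r <- refine_uniform(m, project = radial_projection())
  radii <- sqrt(rowSums(r$vertices^2))
  # the dielectric interface shell must still be at radius exactly 1
  expect_true(any(abs(radii - 1) < 1e-12))
  # solute volume converges toward the true ball under projection
  v_proj <- sum(tet_volumes(r)[r$region == "SOLUTE"])
  v_true <- 4 / 3 * pi
  v_coarse <- sum(tet_volumes(m)[m$region == "SOLUTE"])
  expect_lt(abs(v_proj - v_true), abs(v_coarse - v_true))
})

test_that("interior faces are shared by exactly two tets on fixtures", {
  for (m in list(small_born_mesh(), small_box())) {
    adj <- face_adjacency(m)
    n_int <- sum(adj$neighbors > 0L) / 2
    expect_equal(n_int * 2 + adj$n_boundary_faces, 4L * nrow(m$tets))
    # adjacency is symmetric
    nb <- adj$neighbors
    for (s in 1:4) {
      has <- which(nb[, s] > 0L)
      back <- vapply(has, function(t) t %in% nb[nb[t, s], ], TRUE)
      expect_true(all(back))
    }
  }
})

test_that("equivalent edge length inverts the regular-tet volume identity", {
  m <- regular_tet_mesh()
  expect_equal(equivalent_edge_length(m, c(0.5, 0.3, 0.2), 5), 1,
               tolerance = 1e-12)
  # V = 1/(6 sqrt 2) gives edge 1 by definition
  expect_equal((6 * sqrt(2) * (1 / (6 * sqrt(2))))^(1 / 3), 1)
  expect_error(equivalent_edge_length(m, c(100, 0, 0), 1), "no tet centroid")
})
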