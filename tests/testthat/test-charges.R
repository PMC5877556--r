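test_that("barycentric coordinates: vertices, barycentre, linear system", {
  v <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0, 0, 4))
  for (i in 1:4) {
    lam <- barycentric_coords(v, v[i, ])
    expect_equal(lam, as.numeric(1:4 == i), tolerance = 1e-12)
  }
  expect_equal(barycentric_coords(v, colMeans(v)), rep(0.25, 4),
               tolerance = 1e-12)
  # volumetric-ratio result solves the 4x4 linear reconstruction system
  set.seed(31)
  for (k in 1:20) {
    w <- -log(runif(4)); w <- w / sum(w)
    p <- as.numeric(t(v) %*% w)
    lam <- barycentric_coords(v, p)
    expect_equal(lam, w, tolerance = 1e-12)
    A <- rbind(t(v), rep(1, 4))
    expect_equal(as.numeric(solve(A, c(p, 1))), lam, tolerance = 1e-10)
  }
  expect_error(barycentric_coords(v[c(1, 2, 3, 1), ], c(0.1, 0.1, 0.1)),
               "degenerate")
})

test_that("direct load: vertex and barycentre placements, partition of unity", {
  m <- small_born_mesh()
  # charge exactly at the centre vertex -> whole load on that vertex
  mol <- molecule(matrix(0, 1, 3), 2.5, 1)
  b <- direct_load(mol, m)
  expect_equal(sum(b != 0), 1L)
  expect_equal(max(abs(b)), 2.5)
  # charge at a solute tet barycentre -> q/4 on each vertex
  sol <- which(m$region == "SOLUTE")[5]
  bc <- colMeans(m$vertices[m$tets[sol, ], ])
  b2 <- direct_load(molecule(matrix(bc, 1), 1, 1), m)
  expect_equal(sort(b2[b2 != 0]), rep(0.25, 4), tolerance = 1e-9)
  # sums are exact for clusters (partition of unity)
  clu <- make_random_cluster(50, total_charge = -7, radius = 0.6, seed = 8)
  expect_equal(sum(direct_load(clu, m)), -7, tolerance = 1e-12)
  # atom outside the solute region is refused
  expect_error(direct_load(molecule(matrix(c(5, 0, 0), 1), 1, 1), m),
               "outside the solute")
})

test_that("vertex-on-charge assignment honours integral invariance", {
  m <- small_born_mesh()
  tjc <- sum(tet_volumes(m)[apply(m$tets == 1L, 1, any)])
  mol <- molecule(matrix(0, 1, 3), 1, 1)
  cc <- assign_vertex_on_charge(mol, m)
  expect_equal(cc[1], 4 / tjc)                 # c_j = 4 q / |T_j|
  expect_equal(integrate_density(m, cc), 1, tolerance = 1e-12)
  # two charges on two vertices add linearly
  v2 <- m$vertices[2, ]
  mol2 <- molecule(rbind(c(0, 0, 0), v2), c(1, -2), c(1, 1))
  cc2 <- assign_vertex_on_charge(mol2, m)
  expect_equal(integrate_density(m, cc2), -1, tolerance = 1e-12)
  expect_error(assign_vertex_on_charge(
    molecule(matrix(c(0.123, 0.05, 0), 1), 1, 1), m), "coincide")
})

test_that("average assignment spreads equally and rescales exactly", {
  m <- small_born_mesh()
  mol <- molecule(matrix(0, 1, 3), 3, 1)
  # r_cut so small that only the centre vertex qualifies
  cc <- assign_average(mol, m, r_cut = 0.2)
  expect_equal(sum(cc != 0), 1L)
  expect_equal(integrate_density(m, cc), 3, tolerance = 1e-12)
  expect_equal(cc, assign_vertex_on_charge(mol, m), tolerance = 1e-12)
  # wider truncation spheres still conserve charge
  cc2 <- assign_average(mol, m, r_cut = 1.0)
  expect_gt(sum(cc2 != 0), 1L)
  expect_equal(integrate_density(m, cc2), 3, tolerance = 1e-12)
  # an off-vertex charge with a too-small truncation sphere is refused
  off <- molecule(matrix(c(0.11, 0.07, 0.05), 1), 1, 1)
  expect_error(assign_average(off, m, r_cut = 1e-4), "r_cut")
})

test_that("weighted assignment: vertex degeneracy and conservation", {
  m <- small_born_mesh()
  mol <- molecule(matrix(0, 1, 3), 1.7, 1)
  # on a vertex the barycentric weights degenerate to vertex-on-charge
  expect_equal(assign_weighted(mol, m), assign_vertex_on_charge(mol, m),
               tolerance = 1e-9)
  clu <- make_random_cluster(100, total_charge = 13, radius = 0.7, seed = 2)
  cc <- assign_weighted(clu, m)
  expect_equal(integrate_density(m, cc), 13, tolerance = 1e-12)
})

test_that("all assignment methods conserve charge on 100 random placements", {
  mesh <- label_solute(make_box_mesh(rep(-15, 3), rep(15, 3), rep(10, 3)),
                       molecule(matrix(0, 1, 3), 0, 5), margin = 6)
  clu <- make_random_cluster(100, total_charge = -22, radius = 4, seed = 11)
  expect_equal(sum(direct_load(clu, mesh)), -22, tolerance = 1e-12)
  expect_equal(integrate_density(mesh, assign_weighted(clu, mesh)), -22,
               tolerance = 1e-12)
  expect_equal(integrate_density(mesh, assign_average(clu, mesh, 3)), -22,
               tolerance = 1e-12)
  # density load is consistent with the density integral
  cc <- assign_weighted(clu, mesh)
  expect_equal(sum(density_load(mesh, cc)), -22, tolerance = 1e-12)
})

test_that("point location is deterministic and interpolation is P1-exact", {
  m <- small_box()
  f <- function(p) 2 + 3 * p[, 1] - p[, 2] + 0.5 * p[, 3]   # linear field
  u <- f(m$vertices)
  set.seed(6)
  pts <- matrix(runif(60, -9, 9), ncol = 3)
  expect_equal(interpolate_nodal(m, u, pts), f(pts), tolerance = 1e-10)
  # a point on a shared face resolves to the lowest tet index
  tid1 <- locate_points(m, matrix(m$vertices[100, ], 1))
  tid2 <- locate_points(m, matrix(m$vertices[100, ], 1))
  expect_identical(tid1, tid2)
  expect_true(is.na(locate_points(m, matrix(c(50, 0, 0), 1))))
})
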