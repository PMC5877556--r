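test_that("Born fixture: layered shells, region volumes, centre vertex", {
  spec <- born_spec()
  m <- make_born_mesh(spec)
  vol <- tet_volumes(m)
  # faceted icospheres underestimate ball volumes by the chord deficit
  expect_equal(sum(vol), 4 / 3 * pi * 200^3, tolerance = 0.05)
  expect_equal(sum(vol[m$region == "SOLUTE"]), 4 / 3 * pi, tolerance = 0.05)
  expect_equal(m$vertices[1, ], c(0, 0, 0))   # charge site is a vertex
  expect_true(all(vol > 0))
  expect_true(all(m$boundary_marker == "OUTER"))
  radii <- sqrt(rowSums(m$vertices[-1, ]^2))
  expect_equal(max(radii), 200, tolerance = 1e-9)
  expect_true(any(abs(radii - 1) < 1e-12))    # interface is a shell
})

test_that("structured box mesh: counts, markers, translation consistency", {
  n <- c(5, 4, 3)
  m <- make_box_mesh(c(0, 0, 0), c(10, 8, 6), n)
  expect_equal(nrow(m$tets), 6 * prod(n))
  expect_equal(nrow(m$vertices), prod(n + 1))
  expect_equal(sum(tet_volumes(m)), 10 * 8 * 6, tolerance = 1e-9)
  mk <- table(m$boundary_marker)
  expect_equal(as.integer(mk[c("X_MIN", "X_MAX")]), rep(2 * n[2] * n[3], 2))
  expect_equal(as.integer(mk[c("Y_MIN", "Y_MAX")]), rep(2 * n[1] * n[3], 2))
  expect_equal(as.integer(mk[c("BOTTOM", "TOP")]), rep(2 * n[1] * n[2], 2))
  # opposite faces are exact translated copies
  v <- m$vertices
  for (ax in 1:2) {
    lo <- v[abs(v[, ax] - 0) < 1e-9, -ax, drop = FALSE]
    hi <- v[abs(v[, ax] - c(10, 8)[ax]) < 1e-9, -ax, drop = FALSE]
    expect_equal(lo[do.call(order, as.data.frame(lo)), ],
                 hi[do.call(order, as.data.frame(hi)), ],
                 tolerance = 1e-12)
  }
})

test_that("channel fixture: plug geometry, charges inside the wall", {
  sys <- make_channel_system(channel_spec(n = c(12, 12, 18)))
  cen <- tet_centroids(sys$mesh)
  r <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  sol <- sys$mesh$region == "SOLUTE"
  expect_true(all(r[sol] >= 5 - 1e-9 & r[sol] <= 12 + 1e-9))
  expect_true(all(abs(cen[sol, 3]) <= 18 + 1e-9))
  # ring charges lie strictly inside SOLUTE tets
  tid <- locate_points(sys$mesh, sys$mol$positions)
  expect_true(all(sys$mesh$region[tid] == "SOLUTE"))
  expect_equal(net_charge(sys$mol), -4)
  # the pore must not exit through the box sides
  expect_error(make_channel_system(channel_spec(pore_radius = 15)),
               "box")
})

test_that("random clusters are seeded, exact in net charge, in the ball", {
  m1 <- make_random_cluster(778, total_charge = -22, radius = 10, seed = 42)
  expect_equal(net_charge(m1), -22, tolerance = 1e-12)
  expect_equal(nrow(m1$positions), 778L)
  expect_true(all(rowSums(m1$positions^2) <= 100 + 1e-9))
  expect_true(all(m1$radii >= 1 & m1$radii <= 2))
  m2 <- make_random_cluster(778, total_charge = -22, radius = 10, seed = 42)
  expect_identical(m1$positions, m2$positions)
  m3 <- make_random_cluster(778, total_charge = -22, radius = 10, seed = 43)
  expect_false(identical(m1$positions, m3$positions))
  expect_equal(net_charge(m3), -22, tolerance = 1e-12)
  m4 <- make_random_cluster(1, total_charge = 1, seed = 1)
  expect_equal(m4$charges, 1)
})

test_that("cluster generation preserves the caller's RNG state", {
  set.seed(99); before <- .Random.seed
  invisible(make_random_cluster(10, 0, seed = 1))
  expect_identical(.Random.seed, before)
})
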