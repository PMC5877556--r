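test_that("slab labelling relabels solvent only, by centroid band", {
  sys <- small_channel()
  spec <- membrane_spec(-15, 15, 2)
  m <- label_membrane(sys$mesh, spec)
  expect_false(any(m$region[sys$mesh$region == "SOLUTE"] != "SOLUTE"))
  z <- tet_centroids(m)[, 3]
  in_band <- z >= -15 & z <= 15 & sys$mesh$region == "SOLVENT"
  expect_true(all(m$region[in_band] == "MEMBRANE"))
  expect_true(all(m$region[!in_band & sys$mesh$region == "SOLVENT"]
                  == "SOLVENT"))
  # slab below the whole box leaves the mesh unchanged
  m2 <- label_membrane(sys$mesh, membrane_spec(-29.9, -29.5))
  expect_true(all(m2$region[tet_centroids(m2)[, 3] > -29] ==
                  sys$mesh$region[tet_centroids(m2)[, 3] > -29]))
  expect_error(label_membrane(sys$mesh, membrane_spec(-15, 40)), "outside")
})

test_that("slab volume fraction matches the band on a box-only mesh", {
  bx <- make_box_mesh(c(-10, -10, -30), c(10, 10, 30), c(4, 4, 12))
  m <- label_membrane(bx, membrane_spec(-15, 15))
  vol <- tet_volumes(m)
  frac <- sum(vol[m$region == "MEMBRANE"]) / sum(vol)
  expect_equal(frac, 30 / 60, tolerance = 1e-10)
})

test_that("pore detection matches the geometric cylinder, straight and tilted", {
  for (tilt in c(0, 20)) {
    sys <- make_channel_system(channel_spec(n = c(12, 12, 18),
                                            tilt_deg = tilt))
    spec <- membrane_spec(-15, 15)
    m <- label_membrane(sys$mesh, spec)
    pore <- detect_pore(m, spec, seed = "auto")
    cen <- tet_centroids(m)
    th <- tilt * pi / 180; d <- c(sin(th), 0, cos(th))
    s <- cen %*% d
    rr <- sqrt(rowSums((cen - s %*% t(d))^2))
    geo <- which(rr < 5 & cen[, 3] >= -15 & cen[, 3] <= 15 &
                 m$region != "SOLUTE")
    # agreement up to elements within one local edge length of the
    # cylinder wall or the slab faces (staircase classification)
    h <- 40 / 12
    mism <- union(setdiff(pore, geo), setdiff(geo, pore))
    expect_lt(length(mism), 0.02 * length(geo) + 5)
    near_edge <- abs(rr[mism] - 5) < h |
      pmin(abs(cen[mism, 3] + 15), abs(cen[mism, 3] - 15)) < h
    expect_true(all(near_edge))
    expect_gt(length(intersect(pore, geo)), 0.95 * length(geo))
    # restoring the pore recovers the pre-slab solvent connectivity there
    m2 <- apply_pore(m, pore)
    expect_true(all(m2$region[pore] == "SOLVENT"))
  }
})

test_that("pore detection is seed-invariant and rejects bad seeds", {
  sys <- small_channel()
  spec <- membrane_spec(-15, 15)
  m <- label_membrane(sys$mesh, spec)
  p_auto <- detect_pore(m, spec, "auto")
  for (seed in list(c(0, 0, 0), c(2, 1, 8), c(-1, 2, -10)))
    expect_setequal(detect_pore(m, spec, seed), p_auto)
  expect_error(detect_pore(m, spec, c(8.5, 0, 0)), "SOLUTE")
  expect_error(detect_pore(m, spec, c(0, 0, 25)), "not inside the membrane")
})

test_that("an open slab is rejected as not laterally enclosed", {
  bx <- make_box_mesh(c(-10, -10, -20), c(10, 10, 20), c(6, 6, 10))
  spec <- membrane_spec(-10, 10)
  m <- label_membrane(bx, spec)
  expect_error(detect_pore(m, spec, c(0, 0, 0)), "not laterally enclosed")
})

test_that("a capped channel raises a dead-end cavity error", {
  sys <- small_channel()
  spec <- membrane_spec(-15, 15)
  m <- label_membrane(sys$mesh, spec)
  # block the upper half of the pore with solute: no through-path remains
  cen <- tet_centroids(m)
  r <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  cap <- which(r < 5 + 4 & cen[, 3] > 5 & cen[, 3] < 15 &
               m$region != "SOLUTE")
  m$region[cap] <- "SOLUTE"
  expect_error(detect_pore(m, spec, c(0, 0, -5)), "dead-end cavity")
})

test_that("partial pore filling: identity at 0, full fill, band bounds", {
  sys <- small_channel()
  spec <- membrane_spec(-15, 15)
  m <- label_membrane(sys$mesh, spec)
  pore <- detect_pore(m, spec)
  m <- apply_pore(m, pore)
  expect_identical(fill_pore_partial(m, pore, spec, 0)$region, m$region)
  full <- fill_pore_partial(m, pore, spec, 30)
  expect_true(all(full$region[pore] == "MEMBRANE"))
  half <- fill_pore_partial(m, pore, spec, 15)
  z <- tet_centroids(m)[, 3]
  expect_true(all(half$region[pore][abs(z[pore]) <= 7.4] == "MEMBRANE"))
  expect_true(all(half$region[pore][abs(z[pore]) > 7.6] == "SOLVENT"))
  expect_error(fill_pore_partial(m, pore, spec, -1), "hmp")
  expect_error(fill_pore_partial(m, pore, spec, 31), "hmp")
})
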