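## Synthetic mesh and molecule generators: concentric-sphere Born-ion
## meshes (layered icosphere shells, radially graded), structured
## periodic-ready box meshes (Kuhn 6-tet cube split, so opposite box faces
## are exact translated copies), toy membrane-channel systems (annular
## solute plug around a cylindrical, optionally tilted pore) and seeded
## random charge clusters. No external mesher is required.

## ---- icosphere ----------------------------------------------------------

.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

## Subdivide a triangulated sphere `times` times, projecting to the unit
## sphere after each split.
.icosphere <- function(subdiv = 2) {
  s <- .icosahedron()
  for (it in seq_len(subdiv)) {
    v <- s$vertices; f <- s$faces
    nv <- nrow(v)
    key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    e12 <- key(f[, 1], f[, 2]); e13 <- key(f[, 1], f[, 3])
    e23 <- key(f[, 2], f[, 3])
    uk <- sort(unique(c(e12, e13, e23)))
    ua <- floor(uk / (nv + 1)); ub <- uk - ua * (nv + 1)
    mids <- (v[ua, , drop = FALSE] + v[ub, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    m12 <- match(e12, uk) + nv; m13 <- match(e13, uk) + nv
    m23 <- match(e23, uk) + nv
    s <- list(vertices = rbind(v, mids),
              faces = rbind(cbind(f[, 1], m12, m13),
                            cbind(f[, 2], m12, m23),
                            cbind(f[, 3], m13, m23),
                            cbind(m12, m13, m23)))
  }
  s
}

## Conforming 3-tet split of the prism between corresponding triangles of
## two shells. `bot`/`top` are global indices; the split is decided by the
## sorted order of per-shell local ids so adjacent prisms agree.
.prism_tets <- function(bot, top, local) {
  o <- t(apply(matrix(local, ncol = 3), 1, order))
  m <- nrow(bot)
  pick <- function(mat, col) mat[cbind(seq_len(m), col)]
  i <- pick(bot, o[, 1]); j <- pick(bot, o[, 2]); k <- pick(bot, o[, 3])
  I <- pick(top, o[, 1]); J <- pick(top, o[, 2]); K <- pick(top, o[, 3])
  rbind(cbind(i, j, k, I), cbind(j, k, I, J), cbind(k, I, J, K))
}

#' Specification of a Born-ion concentric-sphere mesh
#'
#' A solute sphere of radius `r_in` (unit charge at the centre in the
#' classic single-atom model) enclosed by a large homocentric solvent
#' sphere of radius `r_out`. The mesh is built from layered icosphere
#' shells: `inner_radii` are the shell radii inside the solute (ending at
#' `r_in` exactly, so the dielectric interface is a mesh surface) and
#' `n_outer` geometrically graded shells continue out to `r_out`. The
#' centre is a mesh vertex, which supports the vertex-on-charge treatment.
#'
#' @param r_in solute radius (Angstrom), default 1
#' @param r_out outer boundary radius (Angstrom), default 200
#' @param subdiv icosphere subdivision level (2 gives 162 vertices/shell)
#' @param inner_radii shell radii inside the solute, last must equal `r_in`
#' @param n_outer number of geometrically graded solvent shells
#' @return a list of class `born_spec`
#' @export
born_spec <- function(r_in = 1, r_out = 200, subdiv = 2,
                      inner_radii = c(r_in / 2, r_in), n_outer = 21) {
  stopifnot(r_in < r_out, n_outer >= 1,
            abs(inner_radii[length(inner_radii)] - r_in) < 1e-12,
            all(diff(inner_radii) > 0), inner_radii[1] > 0)
  structure(list(r_in = r_in, r_out = r_out, subdiv = subdiv,
                 inner_radii = inner_radii, n_outer = n_outer),
            class = "born_spec")
}

#' Build a Born-ion concentric-sphere mesh
#'
#' @param spec a [born_spec()]
#' @return a `pb_mesh` with `SOLUTE` ball, `SOLVENT` shell and the outer
#'   boundary faces marked `OUTER`
#' @export
make_born_mesh <- function(spec = born_spec()) {
  sph <- .icosphere(spec$subdiv)
  nsv <- nrow(sph$vertices); nf <- nrow(sph$faces)
  g <- (spec$r_out / spec$r_in)^(1 / spec$n_outer)
  radii <- c(spec$inner_radii, spec$r_in * g^seq_len(spec$n_outer))
  K <- length(radii)
  verts <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(radii, function(r) r * sph$vertices)))
  shell_idx <- function(k) 1L + (k - 1L) * nsv + seq_len(nsv)
  ## centre ball
  s1 <- shell_idx(1)
  tets <- cbind(1L, matrix(s1[sph$faces], ncol = 3))
  ## shell layers
  for (k in seq_len(K - 1)) {
    bot <- matrix(shell_idx(k)[sph$faces], ncol = 3)
    top <- matrix(shell_idx(k + 1)[sph$faces], ncol = 3)
    tets <- rbind(tets, .prism_tets(bot, top, sph$faces))
  }
  n_in <- length(spec$inner_radii)
  region <- c(rep("SOLUTE", nf),                       # centre ball
              rep("SOLUTE", (n_in - 1) * 3 * nf),      # layers inside r_in
              rep("SOLVENT", (K - n_in) * 3 * nf))
  bf <- matrix(shell_idx(K)[sph$faces], ncol = 3)
  tet_mesh(verts, tets, region, bf, rep("OUTER", nf), box = NULL)
}

## ---- structured box -----------------------------------------------------

#' Structured periodic-ready box mesh
#'
#' A regular grid of cubes, each split into six tets by the Kuhn
#' triangulation. Every cube is split identically, so shared faces match
#' and the surface meshes of opposite box faces are exact copies under
#' translation - the property required by the lateral periodic boundary
#' treatment. All tets start labelled `SOLVENT`.
#'
#' @param lower,upper box corners (length-3, Angstrom)
#' @param n number of cubes per direction (length-3 integer)
#' @return a `pb_mesh` with boundary faces marked
#'   `X_MIN`/`X_MAX`/`Y_MIN`/`Y_MAX`/`BOTTOM`/`TOP`
#' @export
make_box_mesh <- function(lower, upper, n) {
  n <- as.integer(rep_len(n, 3))
  stopifnot(all(n >= 1), all(upper > lower))
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  xs <- seq(lower[1], upper[1], length.out = nx + 1)
  ys <- seq(lower[2], upper[2], length.out = ny + 1)
  zs <- seq(lower[3], upper[3], length.out = nz + 1)
  verts <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  vid <- function(i, j, k) i + (nx + 1L) * (j - 1L) + # 1-based grid index
    (nx + 1L) * (ny + 1L) * (k - 1L)
  cubes <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  i <- cubes$i; j <- cubes$j; k <- cubes$k
  c000 <- vid(i, j, k);         c100 <- vid(i + 1L, j, k)
  c010 <- vid(i, j + 1L, k);    c110 <- vid(i + 1L, j + 1L, k)
  c001 <- vid(i, j, k + 1L);    c101 <- vid(i + 1L, j, k + 1L)
  c011 <- vid(i, j + 1L, k + 1L); c111 <- vid(i + 1L, j + 1L, k + 1L)
  ## Kuhn split: 6 tets along monotone paths 000 -> 111
  tets <- rbind(cbind(c000, c100, c110, c111),
                cbind(c000, c100, c101, c111),
                cbind(c000, c010, c110, c111),
                cbind(c000, c010, c011, c111),
                cbind(c000, c001, c101, c111),
                cbind(c000, c001, c011, c111))
  mesh <- tet_mesh(verts, tets, rep("SOLVENT", nrow(tets)),
                   box = list(lower = lower, upper = upper))
  ## boundary faces from the face audit, classified by plane
  adj <- face_adjacency(mesh)
  bnd <- which(adj$neighbors == 0L, arr.ind = TRUE)
  opp <- list(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  bf <- t(vapply(seq_len(nrow(bnd)), function(r) {
    mesh$tets[bnd[r, 1], opp[[bnd[r, 2]]]]
  }, integer(3)))
  tol <- 1e-6 * max(upper - lower)
  onplane <- function(col, val) {
    abs(verts[bf[, 1], col] - val) < tol &
    abs(verts[bf[, 2], col] - val) < tol &
    abs(verts[bf[, 3], col] - val) < tol
  }
  marker <- rep(NA_character_, nrow(bf))
  marker[onplane(1, lower[1])] <- "X_MIN"
  marker[onplane(1, upper[1])] <- "X_MAX"
  marker[onplane(2, lower[2])] <- "Y_MIN"
  marker[onplane(2, upper[2])] <- "Y_MAX"
  marker[onplane(3, lower[3])] <- "BOTTOM"
  marker[onplane(3, upper[3])] <- "TOP"
  if (anyNA(marker)) stop("boundary face not on any box plane")
  tet_mesh(verts, tets, mesh$region, bf, marker,
           box = list(lower = lower, upper = upper))
}

#' Label tets SOLUTE within expanded atom spheres
#'
#' Marks every tet whose centroid lies within `atom radius + margin` of any
#' atom as `SOLUTE`. With a periodic box the distance is computed under the
#' minimum-image convention in x and y, so the labelling is covariant under
#' lattice translations with wraparound.
#'
#' @param mesh a `pb_mesh`
#' @param mol a `pb_molecule`
#' @param margin enlargement of atomic radii (Angstrom); use ~2 local edge
#'   lengths so every atom ends up strictly inside a SOLUTE tet
#' @param periodic use minimum-image distances in x/y (needs `mesh$box`)
#' @return the relabelled `pb_mesh`
#' @export
label_solute <- function(mesh, mol, margin = 4, periodic = FALSE) {
  cen <- tet_centroids(mesh)
  inside <- rep(FALSE, nrow(cen))
  L <- if (periodic) mesh$box$upper - mesh$box$lower else NULL
  for (a in seq_len(nrow(mol$positions))) {
    d <- sweep(cen, 2, mol$positions[a, ])
    if (periodic) for (k in 1:2) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
    inside <- inside | rowSums(d^2) <= (mol$radii[a] + margin)^2
  }
  region <- mesh$region
  region[inside] <- "SOLUTE"
  mesh$region <- region
  mesh
}

## ---- toy channel --------------------------------------------------------

#' Specification of a toy membrane-channel system
#'
#' A periodic box holding an annular "protein" plug: a cylindrical shell of
#' wall thickness `wall` around an open pore of radius `pore_radius`,
#' optionally tilted about the y axis. The pore pierces the slab end-to-end
#' so, after [label_membrane()], [detect_pore()] must recover it. A ring of
#' point charges sits mid-wall.
#'
#' @param box_half half-extent of the box in x and y (Angstrom)
#' @param z_half half-extent in z
#' @param n cubes per direction for [make_box_mesh()]
#' @param z1,z2 membrane slab faces (Angstrom)
#' @param pore_radius open pore radius (Angstrom)
#' @param wall wall (plug annulus) thickness (Angstrom)
#' @param protrude how far the plug extends beyond the slab on each side
#' @param tilt_deg tilt of the pore axis from z, about the y axis (degrees)
#' @param n_charges number of ring charges mid-wall at the plug equator
#' @param total_charge summed ring charge (e)
#' @return a list of class `channel_spec`
#' @export
channel_spec <- function(box_half = 20, z_half = 30, n = c(16, 16, 24),
                         z1 = -15, z2 = 15, pore_radius = 5, wall = 7,
                         protrude = 3, tilt_deg = 0, n_charges = 8,
                         total_charge = -4) {
  stopifnot(z1 < z2, pore_radius > 0, wall > 0)
  structure(as.list(environment()), class = "channel_spec")
}

## signed distance of points from the (possibly tilted) pore axis, and the
## coordinate along the axis
.axis_coords <- function(pts, tilt_deg) {
  th <- tilt_deg * pi / 180
  d <- c(sin(th), 0, cos(th))          # axis direction (through origin)
  s <- pts %*% d                        # along-axis coordinate
  perp <- pts - s %*% t(d)
  list(r = sqrt(rowSums(perp^2)), s = as.numeric(s), dir = d)
}

#' Build a toy membrane-channel mesh and its decorating charges
#'
#' @param spec a [channel_spec()]
#' @return list with elements `mesh` (a `pb_mesh`: SOLUTE plug, SOLVENT
#'   elsewhere; apply [label_membrane()] afterwards) and `mol`
#'   (a `pb_molecule` with the ring charges, strictly inside the plug wall)
#' @export
make_channel_system <- function(spec = channel_spec()) {
  lower <- c(-spec$box_half, -spec$box_half, -spec$z_half)
  upper <- c(spec$box_half, spec$box_half, spec$z_half)
  mesh <- make_box_mesh(lower, upper, spec$n)
  cen <- tet_centroids(mesh)
  ax <- .axis_coords(cen, spec$tilt_deg)
  zlo <- spec$z1 - spec$protrude; zhi <- spec$z2 + spec$protrude
  r_out <- spec$pore_radius + spec$wall
  if (r_out >= spec$box_half)
    stop("plug wall reaches the box sides; enlarge the box")
  in_plug <- ax$r >= spec$pore_radius & ax$r <= r_out &
             cen[, 3] >= zlo & cen[, 3] <= zhi
  mesh$region[in_plug] <- "SOLUTE"
  ## ring of charges mid-wall at the plug equator, rotated with the axis
  rc <- spec$pore_radius + spec$wall / 2
  phi <- 2 * pi * (seq_len(spec$n_charges) - 1) / spec$n_charges
  th <- spec$tilt_deg * pi / 180
  ## orthonormal frame (e1, e2) normal to the axis
  e1 <- c(cos(th), 0, -sin(th)); e2 <- c(0, 1, 0)
  pos <- rc * (cos(phi) %*% t(e1) + sin(phi) %*% t(e2))
  mol <- molecule(pos,
                  rep(spec$total_charge / spec$n_charges, spec$n_charges),
                  rep(1.5, spec$n_charges))
  list(mesh = mesh, mol = mol)
}

## ---- random cluster -----------------------------------------------------

#' Seeded random charge cluster
#'
#' Atoms uniformly distributed in a ball, per-atom charges summing exactly
#' to `total_charge`, radii uniform in [1, 2] Angstrom. Bit-reproducible
#' for a given seed; the caller's RNG state is preserved.
#'
#' @param n_atoms number of atoms
#' @param total_charge exact net charge (e)
#' @param radius ball radius (Angstrom)
#' @param center ball centre
#' @param seed RNG seed
#' @return a `pb_molecule`
#' @export
make_random_cluster <- function(n_atoms, total_charge = 0, radius = 5,
                                center = c(0, 0, 0), seed = 1) {
  stopifnot(n_atoms >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ## rejection-free uniform ball sampling
  u <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * stats::runif(n_atoms)^(1 / 3)
  pos <- sweep(u * r, 2, center, `+`)
  q <- stats::rnorm(n_atoms)
  q <- q - mean(q) + total_charge / n_atoms
  molecule(pos, q, stats::runif(n_atoms, 1, 2))
}
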