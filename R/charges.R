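## Treatments of the singular fixed charges: direct delta integration of
## the weak-form right-hand side, and three nodal charge-assignment
## schemes (vertex-on-charge, average within a truncation sphere, and
## barycentric-weighted). All assignment schemes enforce integral
## invariance: the finite-element integral of the assigned density equals
## the molecular charge.

#' Barycentric coordinates of points in tetrahedra
#'
#' Computed as volumetric ratios: \eqn{\lambda_i} is the volume of the
#' sub-tet formed by the point and the face opposite vertex i, divided by
#' the element volume.
#'
#' @param verts 4 x 3 matrix of tet vertex coordinates
#' @param point length-3 coordinate
#' @return numeric length-4 barycentric coordinates summing to 1
#' @export
barycentric_coords <- function(verts, point) {
  v0 <- .signed_volumes(rbind(verts, point), matrix(1:4, 1))
  if (abs(v0) < 1e-14) stop("degenerate tetrahedron")
  lam <- numeric(4)
  P <- rbind(verts, point)
  for (i in 1:4) {
    idx <- 1:4; idx[i] <- 5L
    lam[i] <- .signed_volumes(P, matrix(idx, 1)) / v0
  }
  lam
}

## Vectorized barycentric coordinates of pts[i,] w.r.t. tets tid[i] of mesh.
.bary_many <- function(mesh, tid, pts) {
  a <- mesh$vertices[mesh$tets[tid, 1L], , drop = FALSE]
  b <- mesh$vertices[mesh$tets[tid, 2L], , drop = FALSE]
  c <- mesh$vertices[mesh$tets[tid, 3L], , drop = FALSE]
  d <- mesh$vertices[mesh$tets[tid, 4L], , drop = FALSE]
  det3 <- function(u, v, w)
    u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
    u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
    u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  v0 <- det3(b - a, c - a, d - a)
  l2 <- det3(pts - a, c - a, d - a) / v0
  l3 <- det3(b - a, pts - a, d - a) / v0
  l4 <- det3(b - a, c - a, pts - a) / v0
  cbind(1 - l2 - l3 - l4, l2, l3, l4)
}

## Map vertex -> incident tet indices (list), cached on the mesh would be
## nicer but meshes are plain lists; recompute where needed.
.vertex_incidence <- function(mesh) {
  m <- nrow(mesh$tets)
  split(rep.int(seq_len(m), 4L), as.vector(mesh$tets))
}

## Total incident-element volume per vertex, |T_j|.
.vertex_volumes <- function(mesh) {
  vol <- tet_volumes(mesh)
  n <- nrow(mesh$vertices)
  tj <- numeric(n)
  for (k in 1:4) {
    s <- rowsum(vol, mesh$tets[, k])
    ids <- as.integer(rownames(s))
    tj[ids] <- tj[ids] + s[, 1]
  }
  tj
}

#' Locate points in a tet mesh
#'
#' Finds, for each query point, a containing tet (barycentric coordinates
#' all >= -1e-9). Uses a nearest-vertex walk: candidate tets incident to
#' the nearest mesh vertex, expanded ring by ring, with an exhaustive
#' bounding-box fallback. Ties on shared faces resolve to the lowest tet
#' index, so the result is deterministic.
#'
#' @param mesh a `pb_mesh`
#' @param pts k x 3 matrix of query points
#' @return integer vector of tet indices (NA where outside the mesh)
#' @export
locate_points <- function(mesh, pts) {
  pts <- matrix(pts, ncol = 3)
  v <- mesh$vertices
  inc <- .vertex_incidence(mesh)
  tol <- -1e-9
  out <- rep(NA_integer_, nrow(pts))
  for (p in seq_len(nrow(pts))) {
    x <- pts[p, ]
    d2 <- (v[, 1] - x[1])^2 + (v[, 2] - x[2])^2 + (v[, 3] - x[3])^2
    cand <- inc[[which.min(d2)]]
    for (ring in 1:3) {
      lam <- .bary_many(mesh, cand, matrix(x, length(cand), 3, byrow = TRUE))
      hit <- cand[apply(lam >= tol, 1, all)]
      if (length(hit)) { out[p] <- min(hit); break }
      cand <- sort(unique(unlist(inc[as.vector(mesh$tets[cand, ])])))
    }
    if (is.na(out[p])) {  # exhaustive fallback with bbox prefilter
      tt <- mesh$tets
      bb <- rep(TRUE, nrow(tt))
      for (k in 1:3) {
        cmin <- pmin(v[tt[, 1], k], v[tt[, 2], k], v[tt[, 3], k], v[tt[, 4], k])
        cmax <- pmax(v[tt[, 1], k], v[tt[, 2], k], v[tt[, 3], k], v[tt[, 4], k])
        bb <- bb & cmin - 1e-9 <= x[k] & x[k] <= cmax + 1e-9
      }
      cand <- which(bb)
      if (length(cand)) {
        lam <- .bary_many(mesh, cand, matrix(x, length(cand), 3, byrow = TRUE))
        hit <- cand[apply(lam >= tol, 1, all)]
        if (length(hit)) out[p] <- min(hit)
      }
    }
  }
  out
}

#' Interpolate a nodal field at points
#' @param mesh a `pb_mesh`
#' @param u nodal values (length = number of vertices)
#' @param pts k x 3 points
#' @return interpolated values (P1 interpolation in the containing tet)
#' @export
interpolate_nodal <- function(mesh, u, pts) {
  pts <- matrix(pts, ncol = 3)
  tid <- locate_points(mesh, pts)
  if (anyNA(tid)) stop("point(s) outside the mesh: ",
                       paste(which(is.na(tid)), collapse = ", "))
  lam <- .bary_many(mesh, tid, pts)
  rowSums(lam * matrix(u[mesh$tets[tid, ]], nrow(pts), 4))
}

## locate atoms, insisting they lie in SOLUTE tets
.locate_atoms_solute <- function(mesh, mol) {
  tid <- locate_points(mesh, mol$positions)
  bad <- which(is.na(tid) | mesh$region[tid] != "SOLUTE")
  if (length(bad))
    stop("atom(s) outside the solute region: ",
         paste(utils::head(bad, 10), collapse = ", "))
  tid
}

#' Direct integration of the singular charges
#'
#' The weak-form right-hand side of the delta sources evaluated exactly:
#' each atom contributes \eqn{q_i \Phi_j(r_i)} to the load of the four
#' vertices of its containing tet (the barycentric coordinates).
#'
#' @param mol a `pb_molecule`; every atom must lie in a SOLUTE tet
#' @param mesh a `pb_mesh`
#' @return numeric per-vertex load vector `b` (units e); sums to the net
#'   charge exactly (partition of unity)
#' @export
direct_load <- function(mol, mesh) {
  tid <- .locate_atoms_solute(mesh, mol)
  lam <- .bary_many(mesh, tid, mol$positions)
  b <- numeric(nrow(mesh$vertices))
  for (k in 1:4) {
    s <- rowsum(mol$charges * lam[, k], mesh$tets[tid, k])
    ids <- as.integer(rownames(s))
    b[ids] <- b[ids] + s[, 1]
  }
  b
}

#' Vertex-on-charge nodal assignment
#'
#' Requires a mesh whose vertices coincide with the atom positions (within
#' 1e-9 Angstrom). The nodal density coefficient at the charge's vertex is
#' \eqn{c_j = 4 q_j / |T_j|} with \eqn{|T_j|} the total volume of elements
#' containing the vertex, which makes the FE integral of the density equal
#' to the charge.
#'
#' @inheritParams direct_load
#' @return numeric per-vertex density coefficients (e per cubic Angstrom)
#' @export
assign_vertex_on_charge <- function(mol, mesh) {
  v <- mesh$vertices
  tj <- .vertex_volumes(mesh)
  cc <- numeric(nrow(v))
  for (a in seq_len(nrow(mol$positions))) {
    x <- mol$positions[a, ]
    d2 <- (v[, 1] - x[1])^2 + (v[, 2] - x[2])^2 + (v[, 3] - x[3])^2
    j <- which.min(d2)
    if (d2[j] > 1e-18)
      stop("atom ", a, " does not coincide with a mesh vertex")
    cc[j] <- cc[j] + 4 * mol$charges[a] / tj[j]
  }
  cc
}

#' Average nodal assignment within a truncation sphere
#'
#' Each charge is spread equally over all mesh vertices within `r_cut`,
#' then rescaled so its FE-integrated density equals the charge.
#'
#' @inheritParams direct_load
#' @param r_cut truncation sphere radius (Angstrom)
#' @return numeric per-vertex density coefficients (e per cubic Angstrom)
#' @export
assign_average <- function(mol, mesh, r_cut = 1.0) {
  v <- mesh$vertices
  tj <- .vertex_volumes(mesh)
  cc <- numeric(nrow(v))
  for (a in seq_len(nrow(mol$positions))) {
    x <- mol$positions[a, ]
    d2 <- (v[, 1] - x[1])^2 + (v[, 2] - x[2])^2 + (v[, 3] - x[3])^2
    sel <- which(d2 <= r_cut^2)
    if (!length(sel))
      stop("no mesh vertex within r_cut of atom ", a,
           "; increase r_cut (local edge length is larger than ", r_cut, ")")
    ## equal provisional coefficients, rescaled for integral invariance:
    ## integral of one unit coefficient at vertex j is |T_j|/4
    cc[sel] <- cc[sel] + 4 * mol$charges[a] / sum(tj[sel])
  }
  cc
}

#' Barycentric-weighted nodal assignment
#'
#' Each charge is assigned to the four vertices of its containing tet with
#' its barycentric coordinates as weights, then scaled by
#' \eqn{4 / \sum_k |T_k| \lambda_k} so the FE integral equals the charge.
#'
#' @inheritParams direct_load
#' @return numeric per-vertex density coefficients (e per cubic Angstrom)
#' @export
assign_weighted <- function(mol, mesh) {
  tid <- .locate_atoms_solute(mesh, mol)
  lam <- .bary_many(mesh, tid, mol$positions)
  tj <- .vertex_volumes(mesh)
  cc <- numeric(nrow(mesh$vertices))
  for (a in seq_along(tid)) {
    vs <- mesh$tets[tid[a], ]
    scale <- 4 / sum(tj[vs] * lam[a, ])
    cc[vs] <- cc[vs] + mol$charges[a] * lam[a, ] * scale
  }
  cc
}

#' FE integral of a nodal density
#'
#' \eqn{\int \rho^* = \sum_j c_j |T_j| / 4} (exact for P1 densities).
#'
#' @param mesh a `pb_mesh`
#' @param coeffs per-vertex density coefficients
#' @return total integrated charge (e)
#' @export
integrate_density <- function(mesh, coeffs) {
  sum(coeffs * .vertex_volumes(mesh)) / 4
}

#' Weak-form load vector of a nodal density
#'
#' \eqn{b_j = \int \rho^* \Phi_j}, i.e. the P1 mass matrix applied to the
#' coefficients (units e).
#'
#' @param mesh a `pb_mesh`
#' @param coeffs per-vertex density coefficients
#' @return per-vertex load vector
#' @export
density_load <- function(mesh, coeffs) {
  vol <- tet_volumes(mesh)
  tt <- mesh$tets
  csum <- coeffs[tt[, 1]] + coeffs[tt[, 2]] + coeffs[tt[, 3]] + coeffs[tt[, 4]]
  b <- numeric(nrow(mesh$vertices))
  for (k in 1:4) {
    ## row of the element mass matrix: V/20 * (2 c_k + sum of others)
    s <- rowsum(vol / 20 * (coeffs[tt[, k]] + csum), tt[, k])
    ids <- as.integer(rownames(s))
    b[ids] <- b[ids] + s[, 1]
  }
  b
}

#' Build the fixed-charge load for a named treatment
#'
#' @param mol a `pb_molecule`
#' @param mesh a `pb_mesh`
#' @param method one of `"direct"`, `"vertex"`, `"average"`, `"weighted"`
#' @param r_cut truncation radius for the average method
#' @return per-vertex load vector \eqn{b_j = \int \rho \Phi_j} in e units
#' @export
charge_load <- function(mol, mesh,
                        method = c("direct", "vertex", "average", "weighted"),
                        r_cut = 1.0) {
  method <- match.arg(method)
  switch(method,
         direct   = direct_load(mol, mesh),
         vertex   = density_load(mesh, assign_vertex_on_charge(mol, mesh)),
         average  = density_load(mesh, assign_average(mol, mesh, r_cut)),
         weighted = density_load(mesh, assign_weighted(mol, mesh)))
}
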