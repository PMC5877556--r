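## Tetrahedral mesh data model, TetGen/VTK I/O, uniform refinement and
## resolution metrics. Vertices are n x 3 (Angstrom), tets m x 4 (1-based
## vertex indices), one region label per tet, boundary faces f x 3 with a
## marker each. z is the membrane normal throughout.

.region_levels <- c("SOLUTE", "SOLVENT", "MEMBRANE")
.marker_levels <- c("TOP", "BOTTOM", "X_MIN", "X_MAX", "Y_MIN", "Y_MAX",
                    "INTERFACE", "OUTER")

#' Construct a tetrahedral mesh
#'
#' The single geometric substrate for the solver: vertex coordinates, tet
#' connectivity, a region label per tet (`SOLUTE`, `SOLVENT` or `MEMBRANE`)
#' and marked boundary faces. Tets are re-oriented to positive signed volume
#' on construction.
#'
#' @param vertices numeric n x 3 matrix of coordinates (Angstrom).
#' @param tets integer m x 4 matrix of 1-based vertex indices.
#' @param region character vector of length m with values in
#'   `SOLUTE`, `SOLVENT`, `MEMBRANE`.
#' @param boundary_faces integer f x 3 matrix of vertex indices (or NULL).
#' @param boundary_marker character vector of length f with values in
#'   `TOP`, `BOTTOM`, `X_MIN`, `X_MAX`, `Y_MIN`, `Y_MAX`, `INTERFACE`, `OUTER`.
#' @param box either NULL (unbounded, e.g. sphere models) or a list with
#'   numeric `lower` and `upper` corners of the periodic box.
#' @return an object of class `pb_mesh`.
#' @export
tet_mesh <- function(vertices, tets, region, boundary_faces = NULL,
                     boundary_marker = NULL, box = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(tets) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(tets) == 4,
            length(region) == nrow(tets))
  if (!all(region %in% .region_levels))
    stop("unknown region label(s): ",
         paste(setdiff(unique(region), .region_levels), collapse = ", "))
  if (max(tets) > nrow(vertices) || min(tets) < 1L)
    stop("tet vertex index out of range")
  ## enforce positive orientation
  v <- .signed_volumes(vertices, tets)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
  }
  if (any(.signed_volumes(vertices, tets) <= 0))
    stop("degenerate (zero-volume) tetrahedron present")
  if (!is.null(boundary_faces)) {
    boundary_faces <- as.matrix(boundary_faces)
    storage.mode(boundary_faces) <- "integer"
    dimnames(boundary_faces) <- NULL
    stopifnot(ncol(boundary_faces) == 3,
              length(boundary_marker) == nrow(boundary_faces))
    if (!all(boundary_marker %in% .marker_levels))
      stop("unknown boundary marker(s): ",
           paste(setdiff(unique(boundary_marker), .marker_levels),
                 collapse = ", "))
  }
  if (!is.null(box)) {
    stopifnot(is.list(box), length(box$lower) == 3, length(box$upper) == 3,
              all(box$upper > box$lower))
  }
  structure(list(vertices = vertices, tets = tets,
                 region = as.character(region),
                 boundary_faces = boundary_faces,
                 boundary_marker = if (is.null(boundary_faces)) NULL
                                   else as.character(boundary_marker),
                 box = box),
            class = "pb_mesh")
}

#' @export
print.pb_mesh <- function(x, ...) {
  cat("pb_mesh:", nrow(x$vertices), "vertices,", nrow(x$tets), "tets\n")
  cat("  regions:",
      paste(sprintf("%s=%d", names(table(x$region)), table(x$region)),
            collapse = ", "), "\n")
  if (!is.null(x$boundary_faces))
    cat("  boundary faces:", nrow(x$boundary_faces), "(",
        paste(unique(x$boundary_marker), collapse = ", "), ")\n")
  if (!is.null(x$box))
    cat("  box: [", paste(x$box$lower, collapse = ", "), "] to [",
        paste(x$box$upper, collapse = ", "), "]\n")
  invisible(x)
}

.signed_volumes <- function(vertices, tets) {
  a <- vertices[tets[, 1L], , drop = FALSE]
  b <- vertices[tets[, 2L], , drop = FALSE] - a
  c <- vertices[tets[, 3L], , drop = FALSE] - a
  d <- vertices[tets[, 4L], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

#' Tet volumes and centroids
#' @param mesh a `pb_mesh`
#' @return numeric vector of volumes (cubic Angstrom)
#' @export
tet_volumes <- function(mesh) .signed_volumes(mesh$vertices, mesh$tets)

#' @rdname tet_volumes
#' @return `tet_centroids`: m x 3 matrix of element centroids
#' @export
tet_centroids <- function(mesh) {
  (mesh$vertices[mesh$tets[, 1L], , drop = FALSE] +
   mesh$vertices[mesh$tets[, 2L], , drop = FALSE] +
   mesh$vertices[mesh$tets[, 3L], , drop = FALSE] +
   mesh$vertices[mesh$tets[, 4L], , drop = FALSE]) / 4
}

## The 4 faces of each tet, opposite vertices 1..4, as one (4m) x 3 matrix.
## Row order: all faces opposite vertex 1, then opposite 2, etc.
.tet_faces <- function(tets) {
  rbind(tets[, c(2L, 3L, 4L), drop = FALSE],
        tets[, c(1L, 3L, 4L), drop = FALSE],
        tets[, c(1L, 2L, 4L), drop = FALSE],
        tets[, c(1L, 2L, 3L), drop = FALSE])
}

## Sort vertex triples row-wise (small fixed-width sort, vectorized).
.sort_rows3 <- function(f) {
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  cbind(lo, mid, hi)
}

#' Face adjacency of a tet mesh
#'
#' Computes, for every tet, its neighbours across each of its four faces
#' (0 where the face is on the mesh boundary), plus an audit of face
#' sharing: every interior face must be shared by exactly two tets and
#' every boundary face by exactly one.
#'
#' @param mesh a `pb_mesh`
#' @return list with `neighbors` (m x 4 integer matrix, 0 = boundary) and
#'   `n_boundary_faces` (count of faces owned by exactly one tet).
#' @export
face_adjacency <- function(mesh) {
  m <- nrow(mesh$tets)
  fs <- .sort_rows3(.tet_faces(mesh$tets))
  tet_of <- rep.int(seq_len(m), 4L)
  slot_of <- rep(1:4, each = m)
  o <- order(fs[, 1], fs[, 2], fs[, 3])
  fs <- fs[o, , drop = FALSE]
  tet_of <- tet_of[o]; slot_of <- slot_of[o]
  same_next <- c(fs[-nrow(fs), 1] == fs[-1, 1] &
                 fs[-nrow(fs), 2] == fs[-1, 2] &
                 fs[-nrow(fs), 3] == fs[-1, 3], FALSE)
  same_prev <- c(FALSE, same_next[-length(same_next)])
  if (any(same_next & same_prev))
    stop("face shared by more than two tets: mesh is not conforming")
  nb <- matrix(0L, m, 4L)
  i <- which(same_next)                  # pairs (i, i+1)
  nb[cbind(tet_of[i], slot_of[i])] <- tet_of[i + 1L]
  nb[cbind(tet_of[i + 1L], slot_of[i + 1L])] <- tet_of[i]
  list(neighbors = nb,
       n_boundary_faces = sum(!same_next & !same_prev))
}

#' Uniformly refine a tet mesh (octasection)
#'
#' Splits every tet into 8 children through its edge midpoints: four corner
#' tets plus a four-tet split of the interior octahedron along its shortest
#' interior diagonal (a quality-preserving choice). Children inherit the
#' parent's region label; boundary faces are split into their four midpoint
#' children with the marker propagated, so the mesh stays conforming.
#'
#' With `project = NULL` edge midpoints are used as-is, which conserves
#' region volumes exactly but freezes any polyhedral approximation of a
#' curved boundary at its coarse shape. For curved fixtures pass a
#' projector such as [radial_projection()], which moves each new vertex
#' onto the curved surface its parent edge approximates, so refinement
#' also converges geometrically.
#'
#' @param mesh a `pb_mesh`
#' @param project optional `function(mid, pa, pb)` mapping the raw edge
#'   midpoints (k x 3) and their parent endpoint coordinates to adjusted
#'   new-vertex positions
#' @return the refined `pb_mesh` (8x tets, 4x boundary faces)
#' @export
refine_uniform <- function(mesh, project = NULL) {
  v <- mesh$vertices; tt <- mesh$tets
  nv <- nrow(v); m <- nrow(tt)
  epairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                 c(2L, 3L), c(2L, 4L), c(3L, 4L))
  ekey <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
  keys <- matrix(0, m, 6)
  for (e in 1:6) keys[, e] <- ekey(tt[, epairs[[e]][1]], tt[, epairs[[e]][2]])
  ukeys <- sort(unique(as.vector(keys)))
  mid_idx <- matrix(match(keys, ukeys), m, 6) + nv   # per-tet midpoint ids
  ua <- floor(ukeys / (nv + 1)); ub <- ukeys - ua * (nv + 1)
  mids <- (v[ua, , drop = FALSE] + v[ub, , drop = FALSE]) / 2
  if (!is.null(project))
    mids <- project(mids, v[ua, , drop = FALSE], v[ub, , drop = FALSE])
  newv <- rbind(v, mids)

  A <- tt[, 1]; B <- tt[, 2]; C <- tt[, 3]; D <- tt[, 4]
  mAB <- mid_idx[, 1]; mAC <- mid_idx[, 2]; mAD <- mid_idx[, 3]
  mBC <- mid_idx[, 4]; mBD <- mid_idx[, 5]; mCD <- mid_idx[, 6]

  corner <- rbind(cbind(A, mAB, mAC, mAD), cbind(B, mAB, mBC, mBD),
                  cbind(C, mAC, mBC, mCD), cbind(D, mAD, mBD, mCD))

  ## interior octahedron: pick the shortest of the 3 diagonals
  dl <- function(i, j) rowSums((newv[i, , drop = FALSE] -
                                newv[j, , drop = FALSE])^2)
  d1 <- dl(mAB, mCD); d2 <- dl(mAC, mBD); d3 <- dl(mAD, mBC)
  choice <- max.col(-cbind(d1, d2, d3), ties.method = "first")
  octa <- matrix(0L, 4L * m, 4L)
  ## equator cycles around each diagonal (consecutive entries adjacent)
  for (ch in 1:3) {
    sel <- which(choice == ch)
    if (!length(sel)) next
    if (ch == 1L) { p <- mAB[sel]; q <- mCD[sel]
      eq <- cbind(mAC[sel], mAD[sel], mBD[sel], mBC[sel]) }
    else if (ch == 2L) { p <- mAC[sel]; q <- mBD[sel]
      eq <- cbind(mAB[sel], mAD[sel], mCD[sel], mBC[sel]) }
    else { p <- mAD[sel]; q <- mBC[sel]
      eq <- cbind(mAB[sel], mAC[sel], mCD[sel], mBD[sel]) }
    for (k in 1:4) {
      rows <- (k - 1L) * m + sel
      octa[rows, ] <- cbind(p, q, eq[, k], eq[, k %% 4L + 1L])
    }
  }
  newt <- rbind(corner, octa)
  ## corner and octa blocks both stack 4 groups of m child tets in tet order
  newr <- c(rep.int(mesh$region, 4L), rep.int(mesh$region, 4L))

  nbf <- NULL; nbm <- NULL
  if (!is.null(mesh$boundary_faces)) {
    bf <- mesh$boundary_faces
    k12 <- ekey(bf[, 1], bf[, 2]); k13 <- ekey(bf[, 1], bf[, 3])
    k23 <- ekey(bf[, 2], bf[, 3])
    m12 <- match(k12, ukeys) + nv; m13 <- match(k13, ukeys) + nv
    m23 <- match(k23, ukeys) + nv
    if (anyNA(c(m12, m13, m23)))
      stop("boundary face edge not found among tet edges")
    nbf <- rbind(cbind(bf[, 1], m12, m13), cbind(bf[, 2], m12, m23),
                 cbind(bf[, 3], m13, m23), cbind(m12, m13, m23))
    nbm <- rep.int(mesh$boundary_marker, 4L)
  }
  tet_mesh(newv, newt, newr, nbf, nbm, mesh$box)
}

#' Radial projector for concentric-sphere meshes
#'
#' Returns a projection function for [refine_uniform()] that places each
#' new vertex at the mean parent radius from `center` along its own
#' direction. On a layered-shell mesh (every vertex on a sphere about the
#' centre) this keeps all shells - including the dielectric interface and
#' the outer boundary - spherical under refinement.
#'
#' @param center sphere centre (length-3)
#' @return a `function(mid, pa, pb)` for `refine_uniform(project = ...)`
#' @export
radial_projection <- function(center = c(0, 0, 0)) {
  function(mid, pa, pb) {
    ra <- sqrt(rowSums(sweep(pa, 2, center)^2))
    rb <- sqrt(rowSums(sweep(pb, 2, center)^2))
    d <- sweep(mid, 2, center)
    rm_ <- sqrt(rowSums(d^2))
    keep <- rm_ < 1e-12          # midpoint at the centre: leave in place
    scale <- ifelse(keep, 1, (ra + rb) / 2 / pmax(rm_, 1e-300))
    sweep(d * scale, 2, center, `+`)
  }
}

#' Equivalent regular-tetrahedron edge length near a point
#'
#' Averages the volume of all tets whose centroid lies inside the sphere
#' `(center, radius)` and returns the edge length `a` of the regular
#' tetrahedron with that mean volume, `a = (6 sqrt(2) Vbar)^(1/3)`.
#' This is the local resolution metric used to compare with cubic finite
#' difference grids; ~0.36 Angstrom corresponds to a 0.25 Angstrom grid.
#'
#' @param mesh a `pb_mesh`
#' @param center sphere centre (length-3)
#' @param radius sphere radius (Angstrom)
#' @return equivalent edge length in Angstrom
#' @export
equivalent_edge_length <- function(mesh, center = c(0, 0, 0), radius = 5) {
  cen <- tet_centroids(mesh)
  d2 <- (cen[, 1] - center[1])^2 + (cen[, 2] - center[2])^2 +
        (cen[, 3] - center[3])^2
  sel <- d2 <= radius^2
  if (!any(sel)) stop("no tet centroid inside the selection sphere")
  vbar <- mean(tet_volumes(mesh)[sel])
  (6 * sqrt(2) * vbar)^(1 / 3)
}
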