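## Lateral (x/y) periodic boundary conditions by DOF identification:
## every vertex on an X_MAX/Y_MAX box face is matched to its translated
## copy on the opposite face and the pair shares one unknown ("stitching").
## z stays non-periodic (Dirichlet on TOP/BOTTOM).

#' Build the lateral periodic DOF identification
#'
#' Requires translation-consistent opposite faces: for every vertex on
#' X_MIN there is exactly one vertex on X_MAX at offset (Lx, 0, 0) within
#' `tol`, and likewise in y. Vertices on box edges belonging to both
#' periodic directions chain to a single master (the X_MIN/Y_MIN copy).
#'
#' @param mesh a `pb_mesh` with a box and marked boundary faces
#' @param tol matching tolerance (default `1e-6 * max(Lx, Ly)`)
#' @return an object of class `periodic_map`: list with `pairs` (two-column
#'   matrix, slave vertex / master vertex), `reduced_dof` (integer vector
#'   mapping every vertex to its reduced unknown) and `n_reduced`
#' @export
build_periodic_map <- function(mesh, tol = NULL) {
  if (is.null(mesh$box)) stop("mesh has no box; cannot be periodic")
  L <- mesh$box$upper - mesh$box$lower
  if (is.null(tol)) tol <- 1e-6 * max(L[1:2])
  n <- nrow(mesh$vertices)
  v <- mesh$vertices
  face_verts <- function(marker)
    sort(unique(as.vector(
      mesh$boundary_faces[mesh$boundary_marker == marker, , drop = FALSE])))

  match_faces <- function(slaves, masters, offset, dir_name) {
    if (length(slaves) != length(masters))
      stop("faces not translation-consistent in ", dir_name,
           ": vertex counts differ (", length(slaves), " vs ",
           length(masters), ")")
    vs <- sweep(v[slaves, , drop = FALSE], 2, offset)
    vm <- v[masters, , drop = FALSE]
    idx <- integer(length(slaves))
    for (i in seq_along(slaves)) {
      d2 <- (vm[, 1] - vs[i, 1])^2 + (vm[, 2] - vs[i, 2])^2 +
            (vm[, 3] - vs[i, 3])^2
      j <- which.min(d2)
      if (d2[j] > tol^2)
        stop("faces not translation-consistent in ", dir_name,
             ": no match for vertex at (",
             paste(signif(v[slaves[i], ], 8), collapse = ", "), ")")
      idx[i] <- j
    }
    if (anyDuplicated(idx))
      stop("faces not translation-consistent in ", dir_name,
           ": two vertices map to the same master")
    cbind(slave = slaves, master = masters[idx])
  }

  master_of <- seq_len(n)
  px <- match_faces(face_verts("X_MAX"), face_verts("X_MIN"),
                    c(L[1], 0, 0), "x")
  master_of[px[, 1]] <- px[, 2]
  py <- match_faces(face_verts("Y_MAX"), face_verts("Y_MIN"),
                    c(0, L[2], 0), "y")
  master_of[py[, 1]] <- py[, 2]
  ## resolve chains (box edge vertices: max/max -> min/max -> min/min)
  repeat {
    nxt <- master_of[master_of]
    if (identical(nxt, master_of)) break
    master_of <- nxt
  }
  roots <- master_of == seq_len(n)
  red <- integer(n)
  red[roots] <- seq_len(sum(roots))
  red[!roots] <- red[master_of[!roots]]
  pairs <- cbind(slave = which(!roots), master = master_of[!roots])
  structure(list(pairs = pairs, reduced_dof = red, n_reduced = sum(roots)),
            class = "periodic_map")
}

#' @export
print.periodic_map <- function(x, ...) {
  cat("periodic_map:", nrow(x$pairs), "slave vertices folded,",
      x$n_reduced, "reduced unknowns\n")
  invisible(x)
}

## n_vertices x n_reduced fold matrix P (u_full = P u_reduced;
## A_red = t(P) A P sums slave rows/columns onto masters).
.fold_matrix <- function(pmap, n) {
  Matrix::sparseMatrix(i = seq_len(n), j = pmap$reduced_dof, x = 1,
                       dims = c(n, pmap$n_reduced))
}
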