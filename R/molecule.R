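## PQR parsing, molecule container, rigid motions and Shrake-Rupley SASA.

#' Construct a molecule
#'
#' An ordered set of atoms with positions (Angstrom), partial charges
#' (elementary charges) and radii (Angstrom).
#'
#' @param positions n x 3 numeric matrix
#' @param charges numeric vector length n
#' @param radii numeric vector length n, all > 0
#' @return an object of class `pb_molecule`
#' @export
molecule <- function(positions, charges, radii) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  stopifnot(ncol(positions) == 3,
            length(charges) == nrow(positions),
            length(radii) == nrow(positions),
            all(is.finite(positions)), all(is.finite(charges)),
            all(radii > 0))
  structure(list(positions = positions, charges = as.numeric(charges),
                 radii = as.numeric(radii)),
            class = "pb_molecule")
}

#' @export
print.pb_molecule <- function(x, ...) {
  cat("pb_molecule:", nrow(x$positions), "atoms, net charge",
      format(net_charge(x)), "e\n")
  invisible(x)
}

#' Net charge of a molecule
#' @param mol a `pb_molecule`
#' @return sum of atomic partial charges (e)
#' @export
net_charge <- function(mol) sum(mol$charges)

#' Read a PQR file (APBS whitespace dialect)
#'
#' Parses ATOM/HETATM records; `TER`, `REMARK` and `END` lines are ignored.
#' Both the chain-ID and no-chain-ID dialects are accepted by taking the
#' last five whitespace-separated numeric fields of each record as
#' x, y, z, charge, radius.
#'
#' @param path PQR file path
#' @return a `pb_molecule` with atoms in file order
#' @export
read_pqr <- function(path) {
  ln <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", ln)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  rows <- which(rec)
  vals <- lapply(rows, function(i) {
    f <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    v <- v[!is.na(v)]
    if (length(v) < 5)
      stop("cannot parse 5 numeric fields (x y z q r) at line ", i,
           " of ", path)
    utils::tail(v, 5)
  })
  vals <- do.call(rbind, vals)
  if (any(vals[, 5] <= 0))
    stop("non-positive atomic radius at line ",
         rows[which(vals[, 5] <= 0)[1]], " of ", path)
  molecule(vals[, 1:3, drop = FALSE], vals[, 4], vals[, 5])
}

#' Write a molecule as a PQR file
#' @param mol a `pb_molecule`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_pqr <- function(mol, path) {
  n <- nrow(mol$positions)
  writeLines(c(sprintf(
    "ATOM  %5d  X   UNK     1    %8.3f%8.3f%8.3f %11.6f %7.4f",
    seq_len(n), mol$positions[, 1], mol$positions[, 2], mol$positions[, 3],
    mol$charges, mol$radii), "END"), path)
  invisible(path)
}

#' Rigid rotation of a molecule about an in-plane axis
#'
#' Rotates all atom positions about an axis through the molecule centroid
#' lying in the membrane (x-y) plane. Used by the tilt-angle scan.
#'
#' @param mol a `pb_molecule`
#' @param angle rotation angle in degrees
#' @param axis length-3 vector with zero z component (membrane plane)
#' @return the rotated `pb_molecule`
#' @export
rotate_molecule <- function(mol, angle, axis = c(1, 0, 0)) {
  stopifnot(length(axis) == 3)
  if (abs(axis[3]) > 1e-12 * max(abs(axis)))
    stop("rotation axis must lie in the x-y (membrane) plane")
  a <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  cen <- colMeans(mol$positions)
  pos <- sweep(mol$positions, 2, cen) %*% t(R)
  molecule(sweep(pos, 2, cen, `+`), mol$charges, mol$radii)
}

#' Translate a molecule, optionally wrapping into a periodic box
#'
#' @param mol a `pb_molecule`
#' @param delta length-3 translation (Angstrom)
#' @param box optional box list (`lower`, `upper`); when given, x and y are
#'   wrapped back into the box (lateral periodicity; z is not periodic)
#' @return the shifted `pb_molecule`
#' @export
shift_molecule <- function(mol, delta, box = NULL) {
  pos <- sweep(mol$positions, 2, delta, `+`)
  if (!is.null(box)) {
    for (k in 1:2) {
      L <- box$upper[k] - box$lower[k]
      pos[, k] <- box$lower[k] + (pos[, k] - box$lower[k]) %% L
    }
  }
  molecule(pos, mol$charges, mol$radii)
}

## Quasi-uniform points on the unit sphere (Fibonacci lattice).
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, distributes `n_points` quasi-uniform points on the sphere
#' of radius `r_i + probe` and counts the fraction not buried inside any
#' other atom's expanded sphere; the area is that fraction times
#' \eqn{4\pi (r_i + probe)^2}.
#'
#' @param mol a `pb_molecule`
#' @param probe probe (solvent) radius in Angstrom, default 1.4
#' @param n_points points per atom sphere (>= 32), default 960
#' @return numeric vector of per-atom areas in square Angstrom
#' @export
compute_sasa <- function(mol, probe = 1.4, n_points = 960) {
  stopifnot(probe >= 0, n_points >= 32)
  n <- nrow(mol$positions)
  sph <- .fibonacci_sphere(n_points)
  rexp <- mol$radii + probe
  areas <- numeric(n)
  ## neighbour prefilter: atoms whose expanded spheres can overlap
  for (i in seq_len(n)) {
    ri <- rexp[i]
    d <- sweep(mol$positions, 2, mol$positions[i, ])
    dist2 <- rowSums(d^2)
    nb <- which(dist2 < (ri + rexp)^2 & seq_len(n) != i)
    if (!length(nb)) { areas[i] <- 4 * pi * ri^2; next }
    pts <- sweep(sph * ri, 2, mol$positions[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sweep(pts, 2, mol$positions[j, ])
      exposed <- exposed & (rowSums(dj^2) >= rexp[j]^2)
      if (!any(exposed)) break
    }
    areas[i] <- 4 * pi * ri^2 * sum(exposed) / n_points
  }
  areas
}
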