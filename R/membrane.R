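## Implicit membrane slab insertion and channel/pore recognition. The slab
## [z1, z2] relabels solvent elements MEMBRANE by centroid; the pore (the
## water-filled passage through a channel protein) is recovered by a
## direction-free flood fill over face adjacency, which handles tilted
## channels without any preferred walking direction.

#' Membrane slab specification
#' @param z1,z2 lower/upper slab faces (Angstrom), `z1 < z2`
#' @param eps_mem membrane relative dielectric
#' @return an object of class `membrane_spec`
#' @export
membrane_spec <- function(z1 = -15, z2 = 15, eps_mem = 2) {
  stopifnot(z1 < z2, eps_mem >= 1)
  structure(list(z1 = z1, z2 = z2, eps_mem = eps_mem),
            class = "membrane_spec")
}

#' Insert the membrane slab into a labelled mesh
#'
#' Every `SOLVENT` tet whose centroid has `z1 <= z <= z2` becomes
#' `MEMBRANE`; `SOLUTE` tets are never relabelled. Note this also fills a
#' water-filled channel - run [detect_pore()] afterwards and relabel the
#' returned elements back to `SOLVENT`.
#'
#' @param mesh a `pb_mesh`
#' @param spec a [membrane_spec()]
#' @return the relabelled `pb_mesh`
#' @export
label_membrane <- function(mesh, spec) {
  if (!is.null(mesh$box) &&
      (spec$z1 < mesh$box$lower[3] || spec$z2 > mesh$box$upper[3]))
    stop("membrane slab extends outside the box in z")
  z <- tet_centroids(mesh)[, 3]
  sel <- mesh$region == "SOLVENT" & z >= spec$z1 & z <= spec$z2
  mesh$region[sel] <- "MEMBRANE"
  mesh
}

#' Detect the channel/pore region inside the membrane slab
#'
#' Starting from a seed point inside the pore, flood-fills the connected
#' component (shared-face adjacency) of non-`SOLUTE` tets whose centroids
#' lie within the slab, and verifies that the component (a) stays
#' laterally enclosed by the solute (a walk that reaches the box sides is
#' bulk membrane, not a channel) and (b) reaches bulk solvent both above
#' `z2` and below `z1` (otherwise it is a dead-end cavity, not a
#' through-going channel). Face adjacency makes the walk direction-free,
#' so tilted channels are found without special handling.
#'
#' @param mesh a slab-labelled `pb_mesh`
#' @param spec the [membrane_spec()] used for labelling
#' @param seed either a length-3 point strictly inside the pore or
#'   `"auto"`: the midpoint of the solute bounding box in x/y at the slab
#'   centre, snapped to the nearest non-`SOLUTE` tet
#' @return integer vector of pore tet indices (to be relabelled `SOLVENT`
#'   by the caller, e.g. via [apply_pore()])
#' @export
detect_pore <- function(mesh, spec, seed = "auto") {
  cen <- tet_centroids(mesh)
  in_slab <- cen[, 3] >= spec$z1 & cen[, 3] <= spec$z2
  eligible <- mesh$region != "SOLUTE" & in_slab

  if (identical(seed, "auto")) {
    sol <- mesh$region == "SOLUTE"
    if (!any(sol)) stop("auto seeding needs a SOLUTE region")
    bb <- cen[sol, , drop = FALSE]
    pt <- c(mean(range(bb[, 1])), mean(range(bb[, 2])),
            (spec$z1 + spec$z2) / 2)
    cand <- which(eligible)
    d2 <- rowSums(sweep(cen[cand, , drop = FALSE], 2, pt)^2)
    seed_tet <- cand[which.min(d2)]
  } else {
    seed_tet <- locate_points(mesh, matrix(seed, 1))
    if (is.na(seed_tet)) stop("seed point outside the mesh")
    if (mesh$region[seed_tet] == "SOLUTE")
      stop("seed point lies inside the SOLUTE region")
    if (!in_slab[seed_tet])
      stop("seed point is not inside the membrane slab")
  }

  nb <- face_adjacency(mesh)$neighbors
  ## BFS over eligible tets
  visited <- logical(nrow(mesh$tets))
  visited[seed_tet] <- TRUE
  frontier <- seed_tet
  while (length(frontier)) {
    nxt <- unique(as.vector(nb[frontier, , drop = FALSE]))
    nxt <- nxt[nxt > 0L]
    nxt <- nxt[eligible[nxt] & !visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  comp <- which(visited)
  ## a channel is laterally enclosed by the protein; a component reaching
  ## the box sides is bulk membrane, not a pore
  if (!is.null(mesh$box)) {
    tolxy <- 1e-9 * max(mesh$box$upper - mesh$box$lower)
    cv <- mesh$vertices[unique(as.vector(mesh$tets[comp, , drop = FALSE])), ,
                        drop = FALSE]
    hits_side <- any(cv[, 1] < mesh$box$lower[1] + tolxy |
                     cv[, 1] > mesh$box$upper[1] - tolxy |
                     cv[, 2] < mesh$box$lower[2] + tolxy |
                     cv[, 2] > mesh$box$upper[2] - tolxy)
    if (hits_side)
      stop("region is not laterally enclosed by the solute: ",
           "the walk reached the box sides (no channel found)")
  }
  ## must touch non-SOLUTE tets beyond both slab faces
  outside <- mesh$region != "SOLUTE" & !in_slab
  nb_out <- as.vector(nb[comp, , drop = FALSE])
  nb_out <- nb_out[nb_out > 0L]
  nb_out <- nb_out[outside[nb_out]]
  above <- any(cen[nb_out, 3] > spec$z2)
  below <- any(cen[nb_out, 3] < spec$z1)
  if (!(above && below))
    stop("dead-end cavity: component does not reach solvent on both ",
         "sides of the slab")
  comp
}

#' Relabel detected pore elements back to SOLVENT
#' @param mesh a `pb_mesh`
#' @param pore integer tet indices from [detect_pore()]
#' @return the relabelled `pb_mesh`
#' @export
apply_pore <- function(mesh, pore) {
  if (any(mesh$region[pore] == "SOLUTE"))
    stop("pore set contains SOLUTE elements")
  mesh$region[pore] <- "SOLVENT"
  mesh
}

#' Partially fill the pore with membrane (HMP control experiment)
#'
#' Labels pore tets within a central band of height `hmp` (centred at the
#' slab midplane) as `MEMBRANE`, emulating a failure to recognise part of
#' the channel. `hmp = 0` is the identity; `hmp = z2 - z1` fills the whole
#' pore.
#'
#' @param mesh a `pb_mesh` with the pore relabelled `SOLVENT`
#' @param pore integer tet indices of the pore
#' @param spec the [membrane_spec()]
#' @param hmp height of membrane in pore, 0 <= hmp <= z2 - z1 (Angstrom)
#' @return the relabelled `pb_mesh`
#' @export
fill_pore_partial <- function(mesh, pore, spec, hmp) {
  thick <- spec$z2 - spec$z1
  if (hmp < 0 || hmp > thick)
    stop("hmp must be between 0 and the slab thickness (", thick, ")")
  if (hmp == 0) return(mesh)
  zc <- (spec$z1 + spec$z2) / 2
  z <- tet_centroids(mesh)[pore, 3]
  band <- pore[z >= zc - hmp / 2 & z <= zc + hmp / 2]
  mesh$region[band] <- "MEMBRANE"
  mesh
}
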