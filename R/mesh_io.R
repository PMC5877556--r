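## TetGen-style .node/.ele/.face ASCII reading and writing, plus legacy VTK
## unstructured-grid export. The node-file header decides the index base on
## read (TetGen emits either); writing emits 1-based files.

.default_region_map <- c("1" = "SOLUTE", "2" = "SOLVENT", "3" = "MEMBRANE")
.default_marker_map <- c("1" = "TOP", "2" = "BOTTOM", "3" = "X_MIN",
                         "4" = "X_MAX", "5" = "Y_MIN", "6" = "Y_MAX",
                         "7" = "INTERFACE", "8" = "OUTER")

.read_numeric_lines <- function(path) {
  ln <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", ln)
  list(lines = ln[keep], lineno = which(keep))
}

.parse_fields <- function(line) {
  as.numeric(strsplit(trimws(line), "\\s+")[[1]])
}

#' Read a TetGen-style mesh
#'
#' Reads `.node`, `.ele` and (optionally) `.face` ASCII files. The first
#' vertex index in the node file decides 0- vs 1-based indexing. The `.ele`
#' file must carry a region attribute column, mapped to region labels via
#' `region_map`; the `.face` file boundary markers are mapped via
#' `marker_map`.
#'
#' @param node_path,ele_path,face_path file paths (`face_path` may be NULL)
#' @param region_map named character vector, integer attribute -> region label
#' @param marker_map named character vector, integer marker -> face marker
#' @param box optional box (see [tet_mesh()])
#' @return a `pb_mesh`
#' @export
read_tetgen <- function(node_path, ele_path, face_path = NULL,
                        region_map = .default_region_map,
                        marker_map = .default_marker_map,
                        box = NULL) {
  for (p in c(node_path, ele_path, face_path))
    if (!file.exists(p)) stop("no such file: ", p)

  nd <- .read_numeric_lines(node_path)
  hdr <- .parse_fields(nd$lines[1])
  n <- hdr[1]
  if (length(nd$lines) < n + 1) stop("truncated node file: ", node_path)
  vrows <- lapply(nd$lines[2:(n + 1)], .parse_fields)
  idx <- vapply(vrows, `[`, 0, 1L)
  base <- idx[1]
  if (!base %in% c(0, 1)) stop("node file does not start at index 0 or 1")
  verts <- t(vapply(vrows, function(r) r[2:4], numeric(3)))
  ## order by declared index so files need not be sorted
  verts <- verts[order(idx), , drop = FALSE]

  el <- .read_numeric_lines(ele_path)
  ehdr <- .parse_fields(el$lines[1])
  m <- ehdr[1]; nattr <- if (length(ehdr) >= 3) ehdr[3] else 0
  if (nattr < 1)
    stop("ele file carries no region attribute column: ", ele_path)
  if (length(el$lines) < m + 1) stop("truncated ele file: ", ele_path)
  erows <- lapply(el$lines[2:(m + 1)], .parse_fields)
  tets <- t(vapply(erows, function(r) r[2:5], numeric(4))) - base + 1
  attr_col <- vapply(erows, function(r) r[6], 0)
  bad <- which(tets < 1 | tets > n, arr.ind = TRUE)
  if (nrow(bad))
    stop("dangling vertex index in ", ele_path, " line ",
         el$lineno[bad[1, 1] + 1L])
  reg <- region_map[as.character(as.integer(attr_col))]
  if (anyNA(reg))
    stop("region attribute not in region_map in file ", ele_path, ": ",
         paste(unique(attr_col[is.na(reg)]), collapse = ", "))

  bf <- NULL; bm <- NULL
  if (!is.null(face_path)) {
    fc <- .read_numeric_lines(face_path)
    fhdr <- .parse_fields(fc$lines[1])
    nf <- fhdr[1]
    frows <- lapply(fc$lines[2:(nf + 1)], .parse_fields)
    bf <- t(vapply(frows, function(r) r[2:4], numeric(3))) - base + 1
    mk <- vapply(frows, function(r) r[5], 0)
    if (any(bf < 1 | bf > n))
      stop("dangling vertex index in ", face_path)
    bm <- marker_map[as.character(as.integer(mk))]
    if (anyNA(bm))
      stop("boundary marker not in marker_map in file ", face_path)
  }
  tet_mesh(verts, tets, unname(reg), bf, unname(bm), box)
}

#' Write a TetGen-style mesh (1-based indices)
#'
#' @param mesh a `pb_mesh`
#' @param basename path prefix; writes `<basename>.node`, `.ele`, `.face`
#' @param region_map,marker_map label -> integer maps (inverse of the read
#'   maps by default)
#' @return invisibly, the vector of files written
#' @export
write_tetgen <- function(mesh, basename,
                         region_map = .default_region_map,
                         marker_map = .default_marker_map) {
  inv <- function(mp) stats::setNames(as.integer(names(mp)), mp)
  rinv <- inv(region_map); minv <- inv(marker_map)
  n <- nrow(mesh$vertices); m <- nrow(mesh$tets)
  nodef <- paste0(basename, ".node")
  writeLines(c(sprintf("%d 3 0 0", n),
               sprintf("%d %.17g %.17g %.17g", seq_len(n),
                       mesh$vertices[, 1], mesh$vertices[, 2],
                       mesh$vertices[, 3])), nodef)
  elef <- paste0(basename, ".ele")
  writeLines(c(sprintf("%d 4 1", m),
               sprintf("%d %d %d %d %d %d", seq_len(m),
                       mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                       mesh$tets[, 4], rinv[mesh$region])), elef)
  out <- c(nodef, elef)
  if (!is.null(mesh$boundary_faces)) {
    facef <- paste0(basename, ".face")
    nf <- nrow(mesh$boundary_faces)
    writeLines(c(sprintf("%d 1", nf),
                 sprintf("%d %d %d %d %d", seq_len(nf),
                         mesh$boundary_faces[, 1], mesh$boundary_faces[, 2],
                         mesh$boundary_faces[, 3],
                         minv[mesh$boundary_marker])), facef)
    out <- c(out, facef)
  }
  invisible(out)
}

#' Export a mesh (and optionally a nodal field) as legacy VTK
#'
#' Writes an ASCII legacy VTK unstructured grid with the region label as
#' cell data and, if given, a nodal scalar field (e.g. the potential) as
#' point data, for inspection in ParaView.
#'
#' @param mesh a `pb_mesh`
#' @param path output file
#' @param point_data optional named list of nodal numeric vectors
#' @return invisibly, `path`
#' @export
write_vtk <- function(mesh, path, point_data = NULL) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$tets)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0",
               "pbmem tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L,
                     mesh$tets[, 2] - 1L, mesh$tets[, 3] - 1L,
                     mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$region, .region_levels)), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
    }
  }
  invisible(path)
}
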