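#' @useDynLib aneufsi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as
#' @importFrom stats approx optimize setNames
#' @importFrom utils head tail read.csv write.csv
NULL

# row-wise cross product of n x 3 matrices
rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm <- function(a) sqrt(rowSums(a^2))

rowunit <- function(a) a / pmax(rownorm(a), .Machine$double.xmin)

#' Tagged tetrahedral mesh
#'
#' Container for the simplicial meshes used throughout the package: vertices
#' in millimetres, tetrahedral cells, boundary triangles carrying exactly one
#' tag each, and per-cell region labels.  Boundary tags are drawn from
#' \code{"inlet"}, \code{"outlet"}, \code{"interface"} (the fluid-structure
#' interface), \code{"exterior"} (outer wall surface) and \code{"fixed"}
#' (the inflow/outflow plane annuli of the solid).  Regions are
#' \code{"lumen"} for fluid meshes and \code{"artery-wall"} /
#' \code{"bulge-wall"} for solid meshes.
#'
#' Cells are re-oriented to positive signed volume on construction.
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param cells integer m x 4 matrix of 1-based vertex indices.
#' @param boundary_faces integer f x 3 matrix of 1-based vertex indices,
#'   oriented so face normals point out of the mesh.
#' @param boundary_tags character vector of length f, one tag per face.
#' @param region character vector of length m of region labels.
#' @param meta optional list of construction metadata (kept as-is).
#' @return An object of class \code{tagged_mesh}.
#' @export
tagged_mesh <- function(vertices, cells, boundary_faces, boundary_tags,
                        region = rep("lumen", nrow(cells)), meta = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  boundary_faces <- as.matrix(boundary_faces)
  storage.mode(boundary_faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (ncol(cells) != 4L) stop("cells must be m x 4")
  if (nrow(boundary_faces) != length(boundary_tags))
    stop("every boundary face needs exactly one tag")
  if (length(region) != nrow(cells))
    stop("region labels must match the cell count")
  # enforce positive orientation
  vol <- tet_signed_volumes(vertices, cells)
  neg <- which(vol < 0)
  if (length(neg)) cells[neg, c(3L, 4L)] <- cells[neg, c(4L, 3L)]
  if (any(tet_signed_volumes(vertices, cells) <= 0))
    stop("degenerate cell: zero signed volume")
  structure(list(vertices = vertices, cells = cells,
                 boundary_faces = boundary_faces,
                 boundary_tags = as.character(boundary_tags),
                 region = as.character(region), meta = meta),
            class = "tagged_mesh")
}

tet_signed_volumes <- function(V, TT) {
  a <- V[TT[, 1], , drop = FALSE]
  b <- V[TT[, 2], , drop = FALSE] - a
  c2 <- V[TT[, 3], , drop = FALSE] - a
  d <- V[TT[, 4], , drop = FALSE] - a
  rowSums(b * rowcross(c2, d)) / 6
}

#' Cell volumes of a tagged mesh
#' @param mesh a \code{tagged_mesh}.
#' @return numeric vector of tetrahedron volumes in mm^3.
#' @export
mesh_cell_volumes <- function(mesh) {
  tet_signed_volumes(mesh$vertices, mesh$cells)
}

# all 4 outward-oriented facets of every tet: returns (4m x 3) matrix plus
# parent cell index
tet_facets <- function(cells) {
  m <- nrow(cells)
  f1 <- cells[, c(2L, 3L, 4L)]
  f2 <- cells[, c(1L, 4L, 3L)]
  f3 <- cells[, c(1L, 2L, 4L)]
  f4 <- cells[, c(1L, 3L, 2L)]
  faces <- rbind(f1, f2, f3, f4)
  list(faces = faces, cell = rep.int(seq_len(m), 4L))
}

facet_key <- function(faces) {
  s <- t(apply(faces, 1L, sort.int))
  paste(s[, 1], s[, 2], s[, 3], sep = "_")
}

#' Extract the boundary surface of a tetrahedral mesh
#'
#' A facet is on the boundary iff it belongs to exactly one cell; interior
#' facets are shared by exactly two (watertightness).  Returned faces are
#' oriented outward.
#'
#' @param mesh a \code{tagged_mesh} (tags are ignored; only cells are used).
#' @return list with \code{faces} (f x 3, outward), \code{cell} (adjacent
#'   cell index per face).
#' @export
mesh_boundary <- function(mesh) {
  fc <- tet_facets(mesh$cells)
  key <- facet_key(fc$faces)
  tab <- table(key)
  if (any(tab > 2L)) stop("non-manifold mesh: facet shared by > 2 cells")
  bd <- key %in% names(tab)[tab == 1L]
  list(faces = fc$faces[bd, , drop = FALSE], cell = fc$cell[bd])
}

#' Check mesh watertightness
#'
#' Verifies that every interior facet is shared by exactly two cells and
#' every boundary facet by one, and that the tagged boundary faces coincide
#' with the topological boundary.
#'
#' @param mesh a \code{tagged_mesh}.
#' @return \code{TRUE} invisibly; stops with a message otherwise.
#' @export
mesh_check_watertight <- function(mesh) {
  bd <- mesh_boundary(mesh)
  k1 <- sort(facet_key(bd$faces))
  k2 <- sort(facet_key(mesh$boundary_faces))
  if (length(k1) != length(k2) || any(k1 != k2))
    stop("tagged boundary faces do not match the topological boundary")
  invisible(TRUE)
}

# areas (mm^2) and outward unit normals of a face set
face_geometry <- function(V, faces) {
  a <- V[faces[, 1], , drop = FALSE]
  e1 <- V[faces[, 2], , drop = FALSE] - a
  e2 <- V[faces[, 3], , drop = FALSE] - a
  cr <- rowcross(e1, e2)
  nr <- rownorm(cr)
  list(area = nr / 2, normal = cr / pmax(nr, .Machine$double.xmin),
       centroid = (a + V[faces[, 2], , drop = FALSE] +
                     V[faces[, 3], , drop = FALSE]) / 3)
}

# area-weighted outward vertex normals over a face subset; returns matrix
# indexed like V (zero rows off the surface)
vertex_normals <- function(V, faces) {
  fg <- face_geometry(V, faces)
  w <- fg$normal * fg$area
  acc <- matrix(0, nrow(V), 3L)
  for (k in 1:3) {
    rs <- rowsum(w, faces[, k])
    ids <- as.integer(rownames(rs))
    acc[ids, ] <- acc[ids, ] + rs
  }
  rowunit(acc)
}

#' Faces carrying a given boundary tag
#' @param mesh a \code{tagged_mesh}.
#' @param tag one of the boundary tags present in the mesh.
#' @return integer matrix of faces (f x 3).
#' @export
mesh_faces_by_tag <- function(mesh, tag) {
  sel <- mesh$boundary_tags == tag
  if (!any(sel)) stop(sprintf("no boundary faces tagged '%s'", tag))
  mesh$boundary_faces[sel, , drop = FALSE]
}

#' @export
print.tagged_mesh <- function(x, ...) {
  cat("tagged_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$cells), "cells\n")
  cat("  boundary tags:",
      paste(sprintf("%s (%d)", names(table(x$boundary_tags)),
                    as.integer(table(x$boundary_tags))), collapse = ", "),
      "\n")
  cat("  regions:",
      paste(sprintf("%s (%d)", names(table(x$region)),
                    as.integer(table(x$region))), collapse = ", "), "\n")
  invisible(x)
}
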