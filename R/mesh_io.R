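# Gmsh MSH 4.1 (ASCII) input/output with physical groups carrying the
# boundary and region tags, and VTU (XML, ASCII) export for visualization.

msh_tag_order <- c("inlet", "outlet", "interface", "exterior", "fixed")

#' Write a tagged mesh to Gmsh MSH 4.1 (ASCII)
#'
#' Boundary tags become 2D physical groups and region labels 3D physical
#' groups; a write/read round trip preserves vertices, cells and tags.
#'
#' @param mesh a \code{\link{tagged_mesh}}.
#' @param path output file path (conventionally \code{.msh}).
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  V <- mesh$vertices
  btags <- unique(mesh$boundary_tags)
  btags <- btags[order(match(btags, msh_tag_order, nomatch = 99L), btags)]
  rtags <- sort(unique(mesh$region))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w("%d", length(btags) + length(rtags))
  for (i in seq_along(btags)) w("2 %d \"%s\"", i, btags[i])
  for (i in seq_along(rtags))
    w("3 %d \"%s\"", length(btags) + i, rtags[i])
  w("$EndPhysicalNames")
  # one discrete surface entity per boundary tag, one volume per region
  w("$Entities")
  w("0 0 %d %d", length(btags), length(rtags))
  for (i in seq_along(btags))
    w("%d 0 0 0 0 0 0 1 %d 0", i, i)
  for (i in seq_along(rtags))
    w("%d 0 0 0 0 0 0 1 %d 0", i, length(btags) + i)
  w("$EndEntities")
  # nodes: single block on the first volume entity
  n <- nrow(V)
  w("$Nodes")
  w("1 %d 1 %d", n, n)
  w("3 1 0 %d", n)
  writeLines(format(seq_len(n)), con)
  writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
  w("$EndNodes")
  # elements: one block per entity (type 2 = 3-node triangle, 4 = tet)
  nblocks <- length(btags) + length(rtags)
  ntot <- nrow(mesh$boundary_faces) + nrow(mesh$cells)
  w("$Elements")
  w("%d %d 1 %d", nblocks, ntot, ntot)
  eid <- 0L
  for (i in seq_along(btags)) {
    f <- mesh$boundary_faces[mesh$boundary_tags == btags[i], , drop = FALSE]
    w("2 %d 2 %d", i, nrow(f))
    writeLines(sprintf("%d %d %d %d", eid + seq_len(nrow(f)),
                       f[, 1], f[, 2], f[, 3]), con)
    eid <- eid + nrow(f)
  }
  for (i in seq_along(rtags)) {
    tt <- mesh$cells[mesh$region == rtags[i], , drop = FALSE]
    w("3 %d 4 %d", i, nrow(tt))
    writeLines(sprintf("%d %d %d %d %d", eid + seq_len(nrow(tt)),
                       tt[, 1], tt[, 2], tt[, 3], tt[, 4]), con)
    eid <- eid + nrow(tt)
  }
  w("$EndElements")
  invisible(path)
}

#' Read a tagged mesh from Gmsh MSH 4.1 (ASCII)
#'
#' Physical groups of dimension 2 become boundary tags and groups of
#' dimension 3 become region labels.  Files without 2D physical groups are
#' rejected (the solvers need tagged boundaries).
#'
#' @param path path to an ASCII \code{.msh} (format 4.x) file.
#' @return a \code{\link{tagged_mesh}}.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(trimws(sect("MeshFormat")[1]), "\\s+")[[1]]
  if (as.numeric(fmt[1]) < 4 || fmt[2] != "0")
    stop("I/O error: only ASCII MSH format 4.x is supported")
  pn <- sect("PhysicalNames")
  if (is.null(pn)) stop("I/O error: mesh file carries no physical names (no boundary tags)")
  npn <- as.integer(pn[1])
  pdim <- integer(npn); ptag <- integer(npn); pname <- character(npn)
  for (i in seq_len(npn)) {
    tok <- strsplit(trimws(pn[i + 1L]), "\\s+")[[1]]
    pdim[i] <- as.integer(tok[1]); ptag[i] <- as.integer(tok[2])
    pname[i] <- gsub("\"", "", paste(tok[-(1:2)], collapse = " "))
  }
  if (!any(pdim == 2L))
    stop("I/O error: missing 2D physical groups (boundary tags: ",
         paste(msh_tag_order, collapse = ", "), ")")
  # entities: map (dim, entity tag) -> physical tag
  en <- sect("Entities")
  cnt <- as.integer(strsplit(trimws(en[1]), "\\s+")[[1]])
  ent_map <- list()
  row <- 2L
  for (d in 0:3) {
    for (k in seq_len(cnt[d + 1L])) {
      tok <- as.numeric(strsplit(trimws(en[row]), "\\s+")[[1]])
      row <- row + 1L
      if (d >= 2) {
        etag <- as.integer(tok[1])
        nphys <- as.integer(tok[8])
        if (nphys >= 1L)
          ent_map[[paste(d, etag)]] <- as.integer(tok[9])
      }
    }
  }
  # nodes
  nd <- sect("Nodes")
  hdr <- as.numeric(strsplit(trimws(nd[1]), "\\s+")[[1]])
  nnodes <- hdr[2]
  row <- 2L
  ids <- integer(0); coords <- NULL
  while (length(ids) < nnodes) {
    bh <- as.numeric(strsplit(trimws(nd[row]), "\\s+")[[1]])
    nb <- bh[4]
    bids <- as.integer(nd[row + seq_len(nb)])
    bco <- do.call(rbind, lapply(nd[row + nb + seq_len(nb)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])[1:3]))
    ids <- c(ids, bids)
    coords <- rbind(coords, bco)
    row <- row + 2L * nb + 1L
  }
  V <- matrix(0, max(ids), 3L)
  V[ids, ] <- coords
  # elements
  el <- sect("Elements")
  hdr <- as.numeric(strsplit(trimws(el[1]), "\\s+")[[1]])
  nblocks <- hdr[1]
  row <- 2L
  faces <- NULL; ftag <- character(0)
  cells <- NULL; rtag <- character(0)
  for (b in seq_len(nblocks)) {
    bh <- as.numeric(strsplit(trimws(el[row]), "\\s+")[[1]])
    edim <- bh[1]; etag <- bh[2]; etype <- bh[3]; ne <- bh[4]
    dat <- do.call(rbind, lapply(el[row + seq_len(ne)], function(s)
      as.integer(strsplit(trimws(s), "\\s+")[[1]])))
    phys <- ent_map[[paste(edim, etag)]]
    name <- if (!is.null(phys)) pname[pdim == edim & ptag == phys][1] else NA
    if (etype == 2) {          # triangles
      faces <- rbind(faces, dat[, 2:4, drop = FALSE])
      ftag <- c(ftag, rep(if (is.na(name)) "untagged" else name, ne))
    } else if (etype == 4) {   # tets
      cells <- rbind(cells, dat[, 2:5, drop = FALSE])
      rtag <- c(rtag, rep(if (is.na(name)) "lumen" else name, ne))
    }
    row <- row + ne + 1L
  }
  if (is.null(cells)) stop("I/O error: no tetrahedra in mesh file")
  if (is.null(faces)) stop("I/O error: no tagged boundary triangles in mesh file")
  tagged_mesh(V, cells, faces, ftag, region = rtag)
}

#' Export a mesh (with optional vertex fields) to VTU
#'
#' Writes an ASCII XML VTK unstructured grid for visualization; vertex
#' fields are written as point data arrays (vectors as 3 components).
#'
#' @param mesh a \code{\link{tagged_mesh}}.
#' @param path output \code{.vtu} path.
#' @param point_data named list of per-vertex vectors (length n) or
#'   matrices (n x 3).
#' @return the path, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  V <- mesh$vertices
  TT <- mesh$cells
  n <- nrow(V); m <- nrow(TT)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("<?xml version=\"1.0\"?>")
  w("<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" byte_order=\"LittleEndian\">")
  w("<UnstructuredGrid><Piece NumberOfPoints=\"%d\" NumberOfCells=\"%d\">", n, m)
  w("<Points><DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">")
  writeLines(sprintf("%.10g %.10g %.10g", V[, 1], V[, 2], V[, 3]), con)
  w("</DataArray></Points>")
  w("<Cells><DataArray type=\"Int32\" Name=\"connectivity\" format=\"ascii\">")
  writeLines(sprintf("%d %d %d %d", TT[, 1] - 1L, TT[, 2] - 1L,
                     TT[, 3] - 1L, TT[, 4] - 1L), con)
  w("</DataArray><DataArray type=\"Int32\" Name=\"offsets\" format=\"ascii\">")
  writeLines(format(4L * seq_len(m)), con)
  w("</DataArray><DataArray type=\"UInt8\" Name=\"types\" format=\"ascii\">")
  writeLines(rep("10", m), con)
  w("</DataArray></Cells>")
  if (length(point_data)) {
    w("<PointData>")
    for (nm in names(point_data)) {
      d <- point_data[[nm]]
      if (is.matrix(d)) {
        w("<DataArray type=\"Float64\" Name=\"%s\" NumberOfComponents=\"3\" format=\"ascii\">", nm)
        writeLines(sprintf("%.10g %.10g %.10g", d[, 1], d[, 2], d[, 3]), con)
      } else {
        w("<DataArray type=\"Float64\" Name=\"%s\" format=\"ascii\">", nm)
        writeLines(sprintf("%.10g", d), con)
      }
      w("</DataArray>")
    }
    w("</PointData>")
  }
  w("</Piece></UnstructuredGrid></VTKFile>")
  invisible(path)
}
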