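# Structured tetrahedral mesh construction: graded disc lattices swept along
# a (possibly curved) centreline, and shell extrusion along surface normals.
# Prisms are split into tetrahedra with the minimum-global-index rule so that
# shared quadrilateral faces receive the same diagonal in both prisms
# (conforming splits).

# Radial node levels of the cross-section disc, 0 .. R (mm).  Optional
# boundary-layer grading: layer thicknesses grow geometrically from the wall
# (first layer `bl_first`, factor `bl_growth`) until their sum reaches
# `bl_total`; the interior is filled uniformly at ~`core`.
radial_levels <- function(R, core, bl_first = NULL, bl_growth = 1.2,
                          bl_total = NULL) {
  if (!is.null(bl_first) && !is.null(bl_total) && bl_total > 0) {
    if (bl_growth <= 1) stop("bl_growth must exceed 1")
    if (bl_first >= bl_total) stop("bl_first must be below bl_total")
    th <- bl_first
    while (sum(th) < bl_total) th <- c(th, bl_first * bl_growth^length(th))
    if (sum(th) >= R) stop("boundary layer thicker than the radius")
    bl_r <- R - rev(cumsum(th))          # innermost BL node level first
    r_core_max <- bl_r[1]
  } else {
    bl_r <- numeric(0)
    r_core_max <- R
  }
  n_core <- max(2L, ceiling(r_core_max / core))
  core_r <- seq(0, r_core_max, length.out = n_core + 1L)[-1L]
  sort(unique(c(core_r, bl_r, R)))
}

# Triangulate the annulus between an inner ring of n_in nodes and an outer
# ring of n_out nodes (both starting at angle 0, counter-clockwise).  Local
# indices: inner 1..n_in, outer n_in+1..n_in+n_out.  Triangles are CCW.
tri_annulus <- function(n_in, n_out) {
  tris <- matrix(0L, n_in + n_out, 3L)
  ci <- 0L; co <- 0L; k <- 0L
  inner <- function(i) ((i - 1L) %% n_in) + 1L
  outer <- function(j) n_in + ((j - 1L) %% n_out) + 1L
  while (ci < n_in || co < n_out) {
    ang_i <- (ci + 1) / n_in
    ang_o <- (co + 1) / n_out
    k <- k + 1L
    if (co >= n_out || (ci < n_in && ang_i <= ang_o)) {
      tris[k, ] <- c(inner(ci + 1L), outer(co + 1L), inner(ci + 2L))
      ci <- ci + 1L
    } else {
      tris[k, ] <- c(inner(ci + 1L), outer(co + 1L), outer(co + 2L))
      co <- co + 1L
    }
  }
  tris[seq_len(k), , drop = FALSE]
}

# Graded triangulated disc in normalized polar coordinates.
# Returns node table (rhat in [0,1], phi), triangles, and the rim node ids.
disc_lattice <- function(R, core, bl_first = NULL, bl_growth = 1.2,
                         bl_total = NULL, azimuth = core) {
  rl <- radial_levels(R, core, bl_first, bl_growth, bl_total)
  # azimuthal counts: proportional to circumference at the azimuthal target
  # spacing, constant through the boundary layer so BL cells stay prismatic
  spacing <- azimuth
  n_ring <- pmax(6L, as.integer(round(2 * pi * rl / spacing)))
  if (length(rl) > 1L) {
    bl_zone <- if (!is.null(bl_total) && !is.null(bl_first) && bl_total > 0)
      rl > (R - bl_total) * (1 - 1e-9) else rep(FALSE, length(rl))
    if (any(bl_zone) && any(!bl_zone))
      n_ring[bl_zone] <- n_ring[max(which(!bl_zone))]
    n_ring <- cummax(n_ring)  # counts never decrease outward
  }
  rhat <- 0; phi <- 0; level <- 0L
  for (j in seq_along(rl)) {
    ang <- 2 * pi * (seq_len(n_ring[j]) - 1L) / n_ring[j]
    rhat <- c(rhat, rep(rl[j] / R, n_ring[j]))
    phi <- c(phi, ang)
    level <- c(level, rep(j, n_ring[j]))
  }
  start <- cumsum(c(2L, n_ring))  # first node id of each ring (center = 1)
  tris <- NULL
  # center fan
  n1 <- n_ring[1]
  fan <- cbind(1L, start[1] + (seq_len(n1) - 1L),
               start[1] + (seq_len(n1) %% n1))
  tris <- fan
  if (length(rl) > 1L) {
    for (j in seq_len(length(rl) - 1L)) {
      loc <- tri_annulus(n_ring[j], n_ring[j + 1L])
      glob <- c(start[j] + (seq_len(n_ring[j]) - 1L),
                start[j + 1L] + (seq_len(n_ring[j + 1L]) - 1L))
      tris <- rbind(tris, matrix(glob[loc], ncol = 3L))
    }
  }
  rim <- start[length(rl)] + (seq_len(n_ring[length(rl)]) - 1L)
  list(rhat = rhat, phi = phi, level = level, tris = tris, rim = rim,
       n_nodes = length(rhat))
}

# Split prisms (k x 6: bottom a,b,c / top a',b',c' with column i+3 above i)
# into 3 tets each using the minimum-global-index rule.
split_prisms <- function(P) {
  stopifnot(ncol(P) == 6L)
  rot1 <- c(2L, 3L, 1L, 5L, 6L, 4L)
  flip <- c(4L, 6L, 5L, 1L, 3L, 2L)
  amin <- max.col(-P, ties.method = "first")
  Q <- P
  # bring the minimum vertex to position 1
  for (it in 1:2) {            # at most two rotations
    need <- amin %in% c(2L, 3L)
    if (any(need)) {
      Q[need, ] <- Q[need, rot1, drop = FALSE]
      amin <- max.col(-Q, ties.method = "first")
    }
  }
  need <- amin > 3L
  if (any(need)) {
    Q[need, ] <- Q[need, flip, drop = FALSE]
    amin <- max.col(-Q, ties.method = "first")
    for (it in 1:2) {
      need2 <- amin %in% c(2L, 3L)
      if (any(need2)) {
        Q[need2, ] <- Q[need2, rot1, drop = FALSE]
        amin <- max.col(-Q, ties.method = "first")
      }
    }
  }
  stopifnot(all(amin == 1L))
  caseA <- pmin(Q[, 2], Q[, 6]) < pmin(Q[, 3], Q[, 5])
  tets <- matrix(0L, 3L * nrow(Q), 4L)
  ia <- which(caseA); ib <- which(!caseA)
  if (length(ia)) {
    tets[3 * (ia - 1) + 1, ] <- Q[ia, c(1L, 2L, 3L, 6L), drop = FALSE]
    tets[3 * (ia - 1) + 2, ] <- Q[ia, c(1L, 2L, 6L, 5L), drop = FALSE]
    tets[3 * (ia - 1) + 3, ] <- Q[ia, c(1L, 5L, 6L, 4L), drop = FALSE]
  }
  if (length(ib)) {
    tets[3 * (ib - 1) + 1, ] <- Q[ib, c(1L, 2L, 3L, 5L), drop = FALSE]
    tets[3 * (ib - 1) + 2, ] <- Q[ib, c(1L, 5L, 3L, 6L), drop = FALSE]
    tets[3 * (ib - 1) + 3, ] <- Q[ib, c(1L, 5L, 6L, 4L), drop = FALSE]
  }
  tets
}

# Sweep a disc lattice through `ns + 1` sections.  `map_fn(rhat, phi, s)`
# returns an (n x 3) coordinate matrix for section parameter s in [0, 1].
# Returns a tagged_mesh with inlet (s=0), outlet (s=1) and wall faces tagged.
sweep_disc <- function(disc, svals, map_fn, wall_tag = "interface") {
  np <- disc$n_nodes
  ns <- length(svals) - 1L
  V <- matrix(0, np * (ns + 1L), 3L)
  for (k in 0:ns)
    V[k * np + seq_len(np), ] <- map_fn(disc$rhat, disc$phi, svals[k + 1L])
  ntri <- nrow(disc$tris)
  prisms <- matrix(0L, ntri * ns, 6L)
  for (k in seq_len(ns)) {
    off_b <- (k - 1L) * np
    off_t <- k * np
    prisms[(k - 1L) * ntri + seq_len(ntri), ] <-
      cbind(disc$tris + off_b, disc$tris + off_t)
  }
  cells <- split_prisms(prisms)
  section <- rep(0:ns, each = np)   # per-vertex section index
  mesh0 <- tagged_mesh(V, cells, matrix(integer(0), 0, 3), character(0),
                       region = rep("lumen", nrow(cells)),
                       meta = list(section = section,
                                   rhat = rep(disc$rhat, ns + 1L),
                                   phi = rep(disc$phi, ns + 1L),
                                   rim = disc$rim, np = np, ns = ns))
  bd <- mesh_boundary(mesh0)
  f <- bd$faces
  fs <- matrix(section[f], ncol = 3L)
  tag <- rep(wall_tag, nrow(f))
  tag[rowSums(fs == 0L) == 3L] <- "inlet"
  tag[rowSums(fs == ns) == 3L] <- "outlet"
  tagged_mesh(V, cells, f, tag, region = rep("lumen", nrow(cells)),
              meta = mesh0$meta)
}

# Extrude a triangulated surface along outward vertex normals into a layered
# shell (solid wall mesh).  `thicknesses` are the per-layer thicknesses (mm).
# The bottom shell reproduces the given triangulation exactly (conforming
# interface); lateral boundary faces are tagged "fixed", the top "exterior",
# the bottom "interface".
extrude_shell <- function(V, faces, thicknesses, region_fun = NULL,
                          clamp_planes_y = 0) {
  used <- sort(unique(as.integer(faces)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  sV <- V[used, , drop = FALSE]
  sF <- matrix(remap[faces], ncol = 3L)
  nrm <- vertex_normals(sV, sF)
  # keep end annuli coplanar: normals of vertices on the given y planes
  # stay in-plane
  for (yp in clamp_planes_y) {
    on_pl <- abs(sV[, 2] - yp) < 1e-9
    if (any(on_pl)) {
      nrm[on_pl, 2] <- 0
      nrm[on_pl, ] <- rowunit(nrm[on_pl, , drop = FALSE])
    }
  }
  if (any(rownorm(nrm) < 0.5))
    stop("degenerate surface normal during shell extrusion")
  np <- nrow(sV)
  nl <- length(thicknesses)
  offs <- c(0, cumsum(thicknesses))
  Vs <- do.call(rbind, lapply(offs, function(h) sV + h * nrm))
  prisms <- NULL
  for (k in seq_len(nl)) {
    off_b <- (k - 1L) * np
    off_t <- k * np
    prisms <- rbind(prisms, cbind(sF + off_b, sF + off_t))
  }
  cells <- split_prisms(prisms)
  layer <- rep(0:nl, each = np)
  mesh0 <- tagged_mesh(Vs, cells, matrix(integer(0), 0, 3), character(0),
                       region = rep("artery-wall", nrow(cells)),
                       meta = list(layer = layer, np = np, nl = nl,
                                   base_ids = used))
  bd <- mesh_boundary(mesh0)
  f <- bd$faces
  fl <- matrix(layer[f], ncol = 3L)
  tag <- rep("fixed", nrow(f))
  tag[rowSums(fl == 0L) == 3L] <- "interface"
  tag[rowSums(fl == nl) == 3L] <- "exterior"
  region <- rep("artery-wall", nrow(cells))
  if (!is.null(region_fun)) region <- region_fun(Vs, cells)
  tagged_mesh(Vs, cells, f, tag, region = region, meta = mesh0$meta)
}

#' Straight circular tube verification fixture
#'
#' Builds a structured tetrahedral mesh of a straight tube of given radius
#' and length along the y axis (inlet disc at y = 0, outlet at y = L), used
#' by the analytic Poiseuille/Womersley flow oracles and, with
#' \code{\link{make_tube_shell}}, by the elastic pressure-wave fixture.
#'
#' @param radius tube radius in mm.
#' @param length tube length in mm.
#' @param resolution positive scale factor: 1 gives a coarse verification
#'   mesh (~4 elements across the radius); larger values refine.
#' @param n_bl number of geometric boundary-layer rings near the wall
#'   (0 disables the layer).
#' @param wall_tag tag given to the lateral wall faces (default
#'   \code{"interface"} so the mesh can be used directly in coupled runs).
#' @return a \code{\link{tagged_mesh}} of the fluid domain.
#' @export
make_tube_fixture <- function(radius, length, resolution = 1,
                              n_bl = 0L, wall_tag = "interface") {
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be positive")
  if (radius <= 0 || length <= 0) stop("tube dimensions must be positive")
  core <- radius / (2.2 * resolution)
  bl_first <- NULL; bl_total <- NULL
  if (n_bl > 0L) {
    bl_total <- 0.15 * radius
    bl_first <- bl_total * (1.2 - 1) / (1.2^n_bl - 1)
  }
  disc <- disc_lattice(radius, core, bl_first = bl_first,
                       bl_growth = 1.2, bl_total = bl_total)
  ns <- max(3L, ceiling(length / core))
  svals <- seq(0, 1, length.out = ns + 1L)
  map_fn <- function(rhat, phi, s)
    cbind(rhat * radius * cos(phi), s * length, rhat * radius * sin(phi))
  mesh <- sweep_disc(disc, svals, map_fn, wall_tag = wall_tag)
  mesh$meta$radius <- radius
  mesh$meta$length <- length
  mesh
}

#' Elastic shell companion of the tube fixture
#'
#' Extrudes the wall surface of a fluid tube mesh outward into a layered
#' solid shell with a conforming interface triangulation, for coupled
#' (pressure-wave) verification runs.
#'
#' @param fluid_mesh a tube mesh from \code{\link{make_tube_fixture}}.
#' @param thickness total wall thickness in mm.
#' @param layers number of through-thickness element layers.
#' @return a \code{\link{tagged_mesh}} of the solid domain.
#' @export
make_tube_shell <- function(fluid_mesh, thickness = 0.25, layers = 2L) {
  faces <- mesh_faces_by_tag(fluid_mesh, "interface")
  extrude_shell(fluid_mesh$vertices, faces,
                rep(thickness / layers, layers),
                clamp_planes_y = c(0, fluid_mesh$meta$length %||% 0))
}

#' Structured box mesh (verification fixture)
#'
#' Axis-aligned box split into tetrahedra (each lattice cube into 6 via the
#' min-index prism rule on two prisms), with boundary faces tagged by the
#' face of the box they lie on: \code{"xmin"}, \code{"xmax"}, \code{"ymin"},
#' \code{"ymax"}, \code{"zmin"}, \code{"zmax"}.  Used by the small-strain
#' patch test and the mesh-motion diffusion oracle.
#'
#' @param lx,ly,lz box edge lengths, mm.
#' @param nx,ny,nz lattice cell counts per direction.
#' @return a \code{\link{tagged_mesh}}.
#' @export
make_box_mesh <- function(lx = 1, ly = 1, lz = 1, nx = 3L, ny = 3L,
                          nz = 3L) {
  gx <- seq(0, lx, length.out = nx + 1L)
  gy <- seq(0, ly, length.out = ny + 1L)
  gz <- seq(0, lz, length.out = nz + 1L)
  idx <- function(i, jj, k) ((k - 1L) * (ny + 1L) + (jj - 1L)) * (nx + 1L) + i
  V <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  colnames(V) <- NULL
  prisms <- NULL
  for (k in seq_len(nz)) for (jj in seq_len(ny)) for (i in seq_len(nx)) {
    v000 <- idx(i, jj, k);     v100 <- idx(i + 1L, jj, k)
    v010 <- idx(i, jj + 1L, k); v110 <- idx(i + 1L, jj + 1L, k)
    v001 <- idx(i, jj, k + 1L); v101 <- idx(i + 1L, jj, k + 1L)
    v011 <- idx(i, jj + 1L, k + 1L); v111 <- idx(i + 1L, jj + 1L, k + 1L)
    # split the cube into two prisms along the (x,y) diagonal, extruded in z
    prisms <- rbind(prisms,
                    c(v000, v100, v110, v001, v101, v111),
                    c(v000, v110, v010, v001, v111, v011))
  }
  cells <- split_prisms(prisms)
  mesh0 <- tagged_mesh(V, cells, matrix(integer(0), 0, 3), character(0))
  bd <- mesh_boundary(mesh0)
  fc <- face_geometry(V, bd$faces)
  tol <- 1e-9
  tag <- character(nrow(bd$faces))
  tag[abs(fc$centroid[, 1]) < tol] <- "xmin"
  tag[abs(fc$centroid[, 1] - lx) < tol] <- "xmax"
  tag[abs(fc$centroid[, 2]) < tol] <- "ymin"
  tag[abs(fc$centroid[, 2] - ly) < tol] <- "ymax"
  tag[abs(fc$centroid[, 3]) < tol] <- "zmin"
  tag[abs(fc$centroid[, 3] - lz) < tol] <- "zmax"
  tagged_mesh(V, cells, bd$faces, tag)
}

#' Tetrahedral ball mesh (verification fixture)
#'
#' Sphere of given radius meshed by radially layered shells over a
#' subdivided-octahedron surface triangulation, closed by a fan to the
#' centre.  All shell vertices lie exactly on spheres of their level's
#' radius.  Used by the spherical-cap volume oracle.
#'
#' @param radius sphere radius, mm.
#' @param subdiv octahedron-face subdivision level.
#' @param layers radial shell count.
#' @return a \code{\link{tagged_mesh}} with the surface tagged
#'   \code{"exterior"}.
#' @export
make_ball_mesh <- function(radius = 1, subdiv = 6L, layers = 3L) {
  # full octahedron sphere triangulation: 8 octants share subdivided faces
  nmax <- subdiv
  key_pts <- list(); pts <- NULL
  getid <- local({
    env <- new.env(parent = emptyenv())
    function(b) {
      kk <- paste(sprintf("%.12f", b), collapse = ",")
      id <- env[[kk]]
      if (is.null(id)) {
        pts <<- rbind(pts, b)
        id <- nrow(pts)
        env[[kk]] <- id
      }
      id
    }
  })
  tris <- NULL
  for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
    idm <- matrix(0L, nmax + 1L, nmax + 1L)
    for (i in 0:nmax) for (jj in 0:(nmax - i)) {
      b <- c(nmax - i - jj, i, jj) / nmax
      p <- b / sqrt(sum(b^2)) * c(sx, sy, sz)
      idm[i + 1L, jj + 1L] <- getid(p)
    }
    flip <- (sx * sy * sz) < 0
    for (i in 0:(nmax - 1L)) for (jj in 0:(nmax - 1L - i)) {
      t1 <- c(idm[i + 1L, jj + 1L], idm[i + 2L, jj + 1L],
              idm[i + 1L, jj + 2L])
      tris <- rbind(tris, if (flip) t1[c(1, 3, 2)] else t1)
      if (jj < nmax - 1L - i) {
        t2 <- c(idm[i + 2L, jj + 1L], idm[i + 2L, jj + 2L],
                idm[i + 1L, jj + 2L])
        tris <- rbind(tris, if (flip) t2[c(1, 3, 2)] else t2)
      }
    }
  }
  np <- nrow(pts)
  radii <- radius * (layers:1) / layers
  V <- do.call(rbind, lapply(radii, function(rr) pts * rr))
  centre <- np * layers + 1L
  V <- rbind(V, c(0, 0, 0))
  prisms <- NULL
  if (layers > 1L)
    for (k in seq_len(layers - 1L))
      prisms <- rbind(prisms, cbind(tris + k * np, tris + (k - 1L) * np))
  cells <- if (is.null(prisms)) NULL else split_prisms(prisms)
  # innermost shell to the centre
  fan <- cbind(tris + (layers - 1L) * np, centre)
  cells <- rbind(cells, fan)
  mesh0 <- tagged_mesh(V, cells, matrix(integer(0), 0, 3), character(0))
  bd <- mesh_boundary(mesh0)
  tagged_mesh(V, cells, bd$faces, rep("exterior", nrow(bd$faces)))
}
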