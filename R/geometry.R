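# Parametric construction of the idealized sidewall-aneurysm benchmark
# (case R): a perfect sphere intersecting a toroidal parent vessel, with a
# smoothed neck.  Coordinates in mm; the parent vessel centreline is the
# half-circle of radius `torus_major_radius` in the z = 0 plane, running from
# the inlet disc at (-R, 0, 0) to the outlet disc at (+R, 0, 0), both in the
# plane y = 0.  The bulge sphere is centred on the symmetry plane x = 0 at
# height `bulge_center_height` above the inflow plane.

#' Geometry parameters of the sidewall-aneurysm case
#'
#' Lengths in mm.  The torus major radius and bulge sphere radius are
#' figure-derived defaults (the published schematic prints them graphically):
#' with an inlet radius of 2 mm and a torus major radius of 6 mm, the vessel
#' lumen reaches exactly y = 8 mm at its apex, which is consistent with the
#' bulge material occupying the half-space y > 8 mm and the aneurysm centre
#' sitting at y = 10 mm.
#'
#' @param inlet_diameter inlet diameter (default 4).
#' @param wall_thickness arterial wall thickness (default 0.25).
#' @param torus_major_radius centreline radius of the parent vessel
#'   (default 6, figure-derived).
#' @param bulge_radius radius of the spherical bulge (default 2.5,
#'   figure-derived).
#' @param bulge_center_height height of the bulge centre above the
#'   inflow/outflow plane (default 10).
#' @param neck_fillet_radius smoothing length of the neck blend (default 0.5).
#' @param bulge_cut_height plane y = const separating bulge-wall from
#'   artery-wall material (default 8).
#' @return a validated list of class \code{case_geometry_params}.
#' @export
case_geometry_params <- function(inlet_diameter = 4, wall_thickness = 0.25,
                                 torus_major_radius = 6, bulge_radius = 2.5,
                                 bulge_center_height = 10,
                                 neck_fillet_radius = 0.5,
                                 bulge_cut_height = 8) {
  p <- list(inlet_diameter = inlet_diameter, wall_thickness = wall_thickness,
            torus_major_radius = torus_major_radius,
            bulge_radius = bulge_radius,
            bulge_center_height = bulge_center_height,
            neck_fillet_radius = neck_fillet_radius,
            bulge_cut_height = bulge_cut_height)
  if (any(unlist(p) <= 0)) stop("all geometry lengths must be positive")
  if (p$bulge_cut_height >= p$bulge_center_height)
    stop("bulge_cut_height must lie below bulge_center_height")
  if (p$inlet_diameter / 2 >= p$torus_major_radius)
    stop("inlet radius must be below the torus major radius")
  class(p) <- "case_geometry_params"
  p
}

#' Mesh resolution parameters
#'
#' Defaults reproduce the reference-case meshing rules: a fluid boundary
#' layer graded geometrically (factor 1.2) from 0.02 mm to a 0.3 mm total,
#' an isotropic core size of 0.17 mm, and a solid wall divided into 6 equal
#' layers of 0.042 mm.  Since 0.02 mm layers growing by 1.2 never sum to
#' exactly 0.3 mm, layers are added until the cumulative thickness reaches
#' \code{bl_total} (8 layers, ~0.33 mm, at the defaults).
#'
#' @param bl_growth geometric growth factor between layers (> 1).
#' @param bl_first_layer first (wall-adjacent) layer thickness, mm.
#' @param bl_total total boundary-layer thickness, mm.
#' @param core_size isotropic interior element size, mm.
#' @param solid_layers through-thickness element layers in the wall.
#' @param solid_layer_thickness thickness of each solid layer, mm.
#' @return a validated list of class \code{mesh_params}.
#' @export
mesh_params <- function(bl_growth = 1.2, bl_first_layer = 0.02,
                        bl_total = 0.3, core_size = 0.17,
                        solid_layers = 6L, solid_layer_thickness = 0.042) {
  if (bl_growth <= 1) stop("bl_growth must exceed 1")
  if (bl_first_layer >= bl_total) stop("bl_first_layer must be < bl_total")
  p <- list(bl_growth = bl_growth, bl_first_layer = bl_first_layer,
            bl_total = bl_total, core_size = core_size,
            solid_layers = as.integer(solid_layers),
            solid_layer_thickness = solid_layer_thickness)
  class(p) <- "mesh_params"
  p
}

# raw union radius along the ray c(theta) + rho * d(phi): tube radius vs the
# exit distance through the bulge sphere (where the ray enters the sphere
# close enough to the vessel for the sac to be "open" to the lumen)
case_r_rho_raw <- function(theta, phi, p) {
  Rt <- p$torus_major_radius
  r_in <- p$inlet_diameter / 2
  S <- c(0, p$bulge_center_height, 0)
  cx <- Rt * cos(theta); cy <- Rt * sin(theta)
  # d = cos(phi) * u1 + sin(phi) * u2, u1 = (cos t, sin t, 0), u2 = (0,0,1)
  dx <- cos(phi) * cos(theta); dy <- cos(phi) * sin(theta); dz <- sin(phi)
  wx <- S[1] - cx; wy <- S[2] - cy; wz <- S[3]
  proj <- dx * wx + dy * wy + dz * wz
  w2 <- wx^2 + wy^2 + wz^2
  disc <- proj^2 - (w2 - p$bulge_radius^2)
  rho_s <- ifelse(disc > 0, proj + sqrt(pmax(disc, 0)), -Inf)
  entry <- ifelse(disc > 0, proj - sqrt(pmax(disc, 0)), Inf)
  # sac must be open to the lumen along the ray: entry below (blended) tube
  rho_s[entry > r_in + p$neck_fillet_radius] <- -Inf
  pmax(r_in, rho_s)
}

#' Build the case-R solid model
#'
#' Constructs the analytic description of the reference sidewall-aneurysm
#' lumen: a torus-swept circular section unioned with the bulge sphere,
#' represented as a star-shaped radial graph over the centreline and
#' regularized by a small smoothing of the neck region (the sharp
#' tube/sphere intersection angles are smoothed over the
#' \code{neck_fillet_radius} length scale).  The resulting model evaluates
#' the lumen surface radius \code{rho(theta, phi)} for any centreline
#' parameter and azimuth, and is consumed by \code{\link{mesh_fluid}} and
#' \code{\link{mesh_solid}}.
#'
#' @param params a \code{\link{case_geometry_params}} object.
#' @param grid_n resolution of the internal (theta, phi) evaluation grid.
#' @return a list of class \code{case_model} with the smoothed radius
#'   function and the input parameters.
#' @export
build_case_r <- function(params = case_geometry_params(), grid_n = 384L) {
  p <- params
  if (p$bulge_radius <= 1e-12) stop("geometry error: no bulge (radius 0)")
  # neck existence: sphere must reach into the vessel
  apex_gap <- sqrt((p$bulge_center_height - p$torus_major_radius)^2) -
    p$bulge_radius
  if (apex_gap >= p$inlet_diameter / 2)
    stop("geometry error: sphere does not intersect the torus (no neck)")
  if (p$neck_fillet_radius > p$bulge_radius)
    stop("geometry error: fillet radius too large to resolve the neck")
  th <- seq(0, pi, length.out = grid_n + 1L)
  ph <- seq(0, 2 * pi, length.out = 2L * grid_n + 1L)[- (2L * grid_n + 1L)]
  G <- outer(th, ph, function(a, b) case_r_rho_raw(a, b, p))
  # Gaussian smoothing over the (theta, phi) grid at the fillet length scale
  # (phi periodic, theta clamped); arc-length based kernel widths
  sm <- p$neck_fillet_radius
  dth_arc <- (pi / grid_n) * p$torus_major_radius
  dph_arc <- (2 * pi / (2 * grid_n)) * (p$inlet_diameter / 2)
  G <- gauss_smooth_rows(G, sm / dph_arc, periodic = TRUE)          # over phi
  G <- t(gauss_smooth_rows(t(G), sm / dth_arc, periodic = FALSE))   # over theta
  structure(list(params = p, theta = th, phi = ph, rho_grid = G),
            class = "case_model")
}

# separable Gaussian smoothing along rows' second index
gauss_smooth_rows <- function(M, sigma_idx, periodic) {
  if (sigma_idx <= 0) return(M)
  h <- max(1L, ceiling(3 * sigma_idx))
  k <- exp(-0.5 * ((-h:h) / sigma_idx)^2)
  k <- k / sum(k)
  n <- ncol(M)
  out <- matrix(0, nrow(M), n)
  for (j in -h:h) {
    idx <- seq_len(n) + j
    if (periodic) idx <- ((idx - 1L) %% n) + 1L
    else idx <- pmin(pmax(idx, 1L), n)
    out <- out + k[j + h + 1L] * M[, idx, drop = FALSE]
  }
  out
}

# bilinear interpolation of the smoothed radius at arbitrary (theta, phi)
case_r_rho <- function(model, theta, phi) {
  th <- model$theta; ph <- model$phi
  nth <- length(th); nph <- length(ph)
  dth <- th[2] - th[1]; dph <- ph[2] - ph[1]
  it <- pmin(pmax(floor(theta / dth) + 1, 1), nth - 1)
  ft <- pmin(pmax(theta / dth - (it - 1), 0), 1)
  phw <- phi %% (2 * pi)
  ip <- floor(phw / dph) + 1
  fp <- phw / dph - (ip - 1)
  ip2 <- (ip %% nph) + 1
  g <- model$rho_grid
  idx <- function(i, j) g[cbind(i, j)]
  (1 - ft) * ((1 - fp) * idx(it, ip) + fp * idx(it, ip2)) +
    ft * ((1 - fp) * idx(it + 1, ip) + fp * idx(it + 1, ip2))
}

#' Mesh the case-R fluid domain (lumen)
#'
#' Sweeps a boundary-layer-graded disc lattice along the toroidal centreline
#' and maps the rim onto the smoothed lumen surface, producing a structured
#' tetrahedral mesh with tagged inlet (y = 0, x < 0), outlet (y = 0, x > 0)
#' and wall (\code{"interface"}) boundaries.
#'
#' @param model a \code{\link{build_case_r}} model.
#' @param mp a \code{\link{mesh_params}} object.
#' @param scale optional coarsening factor applied to all element sizes
#'   (e.g. 6 gives the desk-scale mesh; 1 is the reference resolution).
#' @return a \code{\link{tagged_mesh}} of the lumen.
#' @export
mesh_fluid <- function(model, mp = mesh_params(), scale = 1) {
  p <- model$params
  r_in <- p$inlet_diameter / 2
  core <- mp$core_size * scale
  bl_first <- mp$bl_first_layer * scale
  bl_total <- mp$bl_total * scale
  if (bl_total >= r_in) stop("boundary layer exceeds the inlet radius")
  disc <- disc_lattice(r_in, core, bl_first = bl_first,
                       bl_growth = mp$bl_growth, bl_total = bl_total)
  arc <- pi * p$torus_major_radius
  ns <- max(8L, ceiling(arc / core))
  svals <- seq(0, 1, length.out = ns + 1L)
  Rt <- p$torus_major_radius
  map_fn <- function(rhat, phi, s) {
    theta <- pi * (1 - s)
    rho <- case_r_rho(model, rep(theta, length(phi)), phi)
    rr <- rhat * rho
    cx <- Rt * cos(theta); cy <- Rt * sin(theta)
    cbind(cx + rr * cos(phi) * cos(theta),
          cy + rr * cos(phi) * sin(theta),
          rr * sin(phi))
  }
  mesh <- sweep_disc(disc, svals, map_fn, wall_tag = "interface")
  mesh$meta$case <- "R"
  mesh$meta$params <- p
  mesh
}

#' Mesh the case-R solid domain (arterial wall)
#'
#' Extrudes the fluid wall surface outward along its normals into
#' \code{solid_layers} equal layers whose total equals the wall thickness,
#' then labels bulge-wall vs artery-wall cells by the cut plane.  The
#' interface triangulation is vertex-identical to the fluid wall
#' triangulation by construction.
#'
#' @param fluid_mesh the matching \code{\link{mesh_fluid}} mesh.
#' @param model the \code{\link{build_case_r}} model (for wall thickness and
#'   cut height).
#' @param mp a \code{\link{mesh_params}} object; the layer count is taken
#'   from \code{solid_layers} and the layer thickness is
#'   \code{wall_thickness / solid_layers}.
#' @return a \code{\link{tagged_mesh}} of the wall.
#' @export
mesh_solid <- function(fluid_mesh, model, mp = mesh_params()) {
  p <- model$params
  nl <- mp$solid_layers
  if (abs(nl * mp$solid_layer_thickness - p$wall_thickness) >
      0.01 * p$wall_thickness + 1e-9)
    warning("solid_layers x solid_layer_thickness differs from wall_thickness by > 1%")
  faces <- mesh_faces_by_tag(fluid_mesh, "interface")
  mesh <- extrude_shell(fluid_mesh$vertices, faces,
                        rep(p$wall_thickness / nl, nl))
  tag_regions(mesh, p$bulge_cut_height)
}

#' Label bulge-wall vs artery-wall cells
#'
#' Wall cells whose centroid lies in the half-space y > \code{cut_height}
#' are labelled \code{"bulge-wall"}; all others \code{"artery-wall"}.
#'
#' @param mesh a solid \code{\link{tagged_mesh}}.
#' @param cut_height cut plane height in mm (default 8).
#' @return the mesh with updated region labels.
#' @export
tag_regions <- function(mesh, cut_height = 8) {
  cen_y <- (mesh$vertices[mesh$cells[, 1], 2] +
              mesh$vertices[mesh$cells[, 2], 2] +
              mesh$vertices[mesh$cells[, 3], 2] +
              mesh$vertices[mesh$cells[, 4], 2]) / 4
  mesh$region <- ifelse(cen_y > cut_height, "bulge-wall", "artery-wall")
  mesh
}
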