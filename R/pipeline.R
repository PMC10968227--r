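# Configuration-driven orchestration: complete rigid or compliant runs of a
# case, metric recording over the second cardiac cycle, and rigid-vs-
# compliant comparison reports.

#' Case configuration
#'
#' Bundles every physical and numerical constant of a benchmark run.  The
#' \code{"desk"} profile uses a coarse structured mesh (about five times
#' coarser than the reference resolution) and dt = 2 ms so a full
#' two-cycle rigid/compliant pair runs on a workstation; the \code{"full"}
#' profile carries the reference meshing rules (boundary layer graded
#' 0.02 mm/factor 1.2/total 0.3 mm, core 0.17 mm, 6 solid layers) and
#' dt = 1 ms, and is intended for cluster-scale replication.
#'
#' @param geometry a \code{\link{case_geometry_params}}.
#' @param fluid a \code{\link{fluid_params}}.
#' @param solid a \code{\link{solid_params}}.
#' @param outlet an \code{\link{outlet_model}}.
#' @param coupling a \code{\link{coupling_config}}.
#' @param target_mean_flow cycle-mean inflow, mL/s.
#' @param period,ramp cardiac period and start-up ramp, s.
#' @param dt time-step size, s (profile default).
#' @param t_end final time, s (default 1.8 = ramp + 2 cycles).
#' @param t0 metric window start, s (default 1.0; window is [t0, t0+T]).
#' @param mode \code{"compliant"} or \code{"rigid"}.
#' @param profile \code{"desk"} or \code{"full"}.
#' @param mesh optional pre-built fluid \code{\link{tagged_mesh}}.
#' @param store_every store metric samples every k-th step.
#' @param output_dir optional directory for CSV/VTU outputs.
#' @return an object of class \code{case_config}.
#' @export
case_config <- function(geometry = case_geometry_params(),
                        fluid = fluid_params(), solid = solid_params(),
                        outlet = outlet_model(),
                        coupling = coupling_config(),
                        target_mean_flow = 4, period = 0.8, ramp = 0.2,
                        dt = NULL, t_end = 1.8, t0 = 1.0,
                        mode = c("compliant", "rigid"),
                        profile = c("desk", "full"),
                        mesh = NULL, store_every = 1L, output_dir = NULL) {
  mode <- match.arg(mode)
  profile <- match.arg(profile)
  if (is.null(dt)) dt <- if (profile == "desk") 2e-3 else 1e-3
  if (dt <= 0) stop("dt must be positive")
  if (t_end < t0 + period - 1e-9)
    stop("t_end must cover the metric window t0 + one period")
  structure(list(geometry = geometry, fluid = fluid, solid = solid,
                 outlet = outlet, coupling = coupling,
                 target_mean_flow = target_mean_flow, period = period,
                 ramp = ramp, dt = dt, t_end = t_end, t0 = t0, mode = mode,
                 profile = profile, mesh = mesh,
                 store_every = as.integer(store_every),
                 output_dir = output_dir),
            class = "case_config")
}

# profile-specific meshing parameters; the desk profile concentrates the
# axial sections around the bulge (theta near pi/2)
profile_mesh_params <- function(profile) {
  if (profile == "full") mesh_params()
  else list(core = 0.9, azimuth = 0.7, sections = 18L,
            solid_layers = 1L)
}

# graded section parameters: denser near the bulge apex
desk_section_svals <- function(ns) {
  th <- seq(0, pi, length.out = 512)
  w <- 1 + 1.5 * exp(-((th - pi / 2) / 0.35)^2)
  cdf <- cumsum(w) / sum(w)
  s <- approx(cdf, seq(0, 1, length.out = 512),
              xout = seq(0, 1, length.out = ns + 1L), rule = 2)$y
  s[1] <- 0; s[ns + 1L] <- 1
  s
}

# build the fluid (and solid) meshes of a config
build_case_meshes <- function(cfg) {
  model <- build_case_r(cfg$geometry)
  if (!is.null(cfg$mesh)) {
    fl <- cfg$mesh
  } else if (cfg$profile == "full") {
    fl <- mesh_fluid(model, mesh_params())
  } else {
    pm <- profile_mesh_params("desk")
    p <- cfg$geometry
    r_in <- p$inlet_diameter / 2
    disc <- disc_lattice(r_in, pm$core, azimuth = pm$azimuth)
    Rt <- p$torus_major_radius
    map_fn <- function(rhat, phi, s) {
      theta <- pi * (1 - s)
      rho <- case_r_rho(model, rep(theta, length(phi)), phi)
      rr <- rhat * rho
      cbind(Rt * cos(theta) + rr * cos(phi) * cos(theta),
            Rt * sin(theta) + rr * cos(phi) * sin(theta),
            rr * sin(phi))
    }
    fl <- sweep_disc(disc, desk_section_svals(pm$sections), map_fn)
  }
  sl <- NULL
  if (cfg$mode == "compliant") {
    nl <- if (cfg$profile == "full") mesh_params()$solid_layers
          else profile_mesh_params("desk")$solid_layers
    faces <- mesh_faces_by_tag(fl, "interface")
    sl <- extrude_shell(fl$vertices, faces,
                        rep(cfg$geometry$wall_thickness / nl, nl))
    sl <- tag_regions(sl, cfg$geometry$bulge_cut_height)
  }
  list(model = model, fluid = fl, solid = sl)
}

#' Run a complete case
#'
#' Time loop over [0, t_end] in rigid (pure CFD, fixed no-slip walls) or
#' compliant (partitioned FSI) mode, recording the haemodynamic metric
#' series over the second cardiac cycle [t0, t0 + T]: inflow rate, outlet
#' pressure, bulge-averaged WSS, swirl rate, lumen volume above the cut
#' plane, wall shear samples for TAWSS/OSI, and (compliant) the maximum
#' interface displacement.
#'
#' @param cfg a \code{\link{case_config}}.
#' @param meshes optional pre-built meshes from an earlier run (so rigid
#'   and compliant runs share the identical fluid mesh).
#' @param verbose print progress every 100 steps.
#' @return a result bundle (class \code{result_bundle}).
#' @export
run_case <- function(cfg, meshes = NULL, verbose = FALSE) {
  if (is.null(meshes)) meshes <- build_case_meshes(cfg)
  fl_mesh <- meshes$fluid
  wf <- build_waveform(target_mean_flow = cfg$target_mean_flow,
                       inlet_area = pi * (cfg$geometry$inlet_diameter / 2)^2,
                       period = cfg$period, ramp = cfg$ramp)
  fls <- fluid_setup(fl_mesh, cfg$fluid, waveform = wf, outlet = cfg$outlet)
  n_f <- fls$n
  compliant <- cfg$mode == "compliant"
  sls <- NULL; imap <- NULL
  if (compliant) {
    if (is.null(meshes$solid)) stop("compliant run needs a solid mesh")
    sls <- solid_setup(meshes$solid, cfg$solid)
    imap <- match_interface(fl_mesh, meshes$solid,
                            fls$interface_nodes, sls$interface_nodes)
  }
  nsteps <- round(cfg$t_end / cfg$dt)
  state <- list(flow = new_flow_state(n_f), flow2 = NULL,
                solid = if (compliant) new_solid_state(sls$n) else NULL,
                solid2 = NULL, d1 = NULL, d2 = NULL)
  rec <- list(times = c(), inflow = c(), p_out = c(), swirl = c(),
              vol = c(), maxdisp = c(), tau = list(), vfield = list(),
              vcoords = list())
  wall_info <- NULL
  iter_log <- NULL
  t0 <- cfg$t0; t1 <- cfg$t0 + cfg$period
  for (k in seq_len(nsteps)) {
    t_new <- k * cfg$dt
    if (!compliant) {
      flow <- advance_fluid(fls, state$flow, state$flow2, t_new, cfg$dt,
                            picard_tol = 1e-5)
      state$flow2 <- state$flow; state$flow <- flow
      Vc <- fls$V
      motion <- NULL
    } else {
      res <- coupled_step(fls, sls, imap, state, t_new, cfg$dt,
                          cfg$coupling)
      state$flow2 <- state$flow; state$flow <- res$flow
      state$solid2 <- state$solid; state$solid <- res$solid
      state$d2 <- state$d1; state$d1 <- res$motion$d_mesh
      Vc <- fls$V + res$motion$d_mesh
      lg <- res$log; lg$t <- t_new
      iter_log <- rbind(iter_log, lg)
      flow <- res$flow
    }
    in_window <- t_new >= t0 - 1e-9 && t_new <= t1 + 1e-9
    if (in_window && (k %% cfg$store_every == 0L)) {
      trc <- fluid_traction(flow, fls, "interface",
                            vertices_current = if (compliant) Vc else NULL)
      wv <- wall_vertex_shear(trc, n_f)
      if (is.null(wall_info))
        wall_info <- list(vertices = wv$vertices,
                          varea = wv$varea[wv$vertices],
                          coords = fl_mesh$vertices[wv$vertices, , drop = FALSE])
      rec$tau[[length(rec$tau) + 1L]] <- wv$tau[wall_info$vertices, , drop = FALSE]
      rec$times <- c(rec$times, t_new)
      rec$inflow <- c(rec$inflow, -flow$Q_in)
      rec$p_out <- c(rec$p_out, flow$P_out)
      rec$swirl <- c(rec$swirl, swirl_rate(Vc, fls$T, flow$v,
                                           cfg$geometry$bulge_center_height))
      geo_c <- fem_p1_geometry(Vc, fls$T)
      rec$vol <- c(rec$vol,
                   fem_volume_above_plane(Vc, fls$T, geo_c$vol,
                                          cfg$geometry$bulge_cut_height * 1e-3) * 1e9)
      rec$maxdisp <- c(rec$maxdisp,
                       if (compliant) max(rownorm(state$solid$u)) * 1e3 else 0)
      rec$vfield[[length(rec$vfield) + 1L]] <- flow$v
      rec$vcoords[[length(rec$vcoords) + 1L]] <- if (compliant) Vc else fls$V
    }
    if (verbose && k %% 100L == 0L)
      message(sprintf("  t = %.3f s (%d/%d)", t_new, k, nsteps))
  }
  nt <- length(rec$times)
  nv <- length(wall_info$vertices)
  tau_arr <- array(0, c(nt, nv, 3))
  for (i in seq_len(nt)) tau_arr[i, , ] <- rec$tau[[i]]
  ws <- wall_series(rec$times, tau_arr, wall_info$vertices,
                    wall_info$varea,
                    normals = NULL, coords = wall_info$coords)
  # diastolic reference: minimum-inflow instant within the window
  iref <- which.min(rec$inflow)
  vol_pct <- 100 * (rec$vol - rec$vol[iref]) / rec$vol[iref]
  bundle <- structure(list(
    config = cfg, times = rec$times, inflow = rec$inflow,
    p_out = rec$p_out, swirl = rec$swirl, vol = rec$vol,
    vol_pct = vol_pct, max_displacement = max(rec$maxdisp),
    wall = ws, TAWSS = tawss(ws), OSI = osi(ws),
    bulge_wss = bulge_avg_wss(ws, cfg$geometry$bulge_cut_height),
    vfield = rec$vfield, vcoords = rec$vcoords,
    iter_log = iter_log, mesh = fl_mesh, cells = fls$T,
    provenance = list(mode = cfg$mode, profile = cfg$profile,
                      dt = cfg$dt, t_end = cfg$t_end,
                      version = as.character(utils::packageVersion("aneufsi")))),
    class = "result_bundle")
  if (!is.null(cfg$output_dir)) write_bundle(bundle, cfg$output_dir)
  bundle
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("result_bundle (%s, %s profile): %d metric samples on [%.2f, %.2f] s\n",
              x$config$mode, x$config$profile, length(x$times),
              min(x$times), max(x$times)))
  cat(sprintf("  peak inflow %.3f mL/s | peak outlet pressure %.3f kPa | peak bulge WSS %.3f Pa\n",
              max(x$inflow), max(x$p_out), max(x$bulge_wss)))
  cat(sprintf("  peak swirl %.4f mL/s | max volume variation %.2f%% | max displacement %.4f mm\n",
              max(x$swirl), max(x$vol_pct), x$max_displacement))
  invisible(x)
}

# CSV/VTU outputs of a bundle
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(t = bundle$times, inflow = bundle$inflow,
                       p_out = bundle$p_out, swirl = bundle$swirl,
                       bulge_wss = bundle$bulge_wss, vol = bundle$vol,
                       vol_pct = bundle$vol_pct),
            file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(bundle$iter_log))
    write.csv(bundle$iter_log, file.path(dir, "iterations.csv"),
              row.names = FALSE)
  tw <- numeric(nrow(bundle$mesh$vertices)); tw[bundle$wall$vertices] <- bundle$TAWSS
  os <- numeric(nrow(bundle$mesh$vertices)); os[bundle$wall$vertices] <- bundle$OSI
  write_vtu(bundle$mesh, file.path(dir, "wall_metrics.vtu"),
            point_data = list(TAWSS = tw, OSI = os))
  invisible(dir)
}

#' Probe a nodal field along a straight line
#'
#' Linear interpolation of a P1 field at sample points (barycentric search
#' over candidate cells).
#'
#' @param vertices mesh vertex coordinates (any units).
#' @param cells tetrahedra.
#' @param field per-vertex values (vector or matrix).
#' @param points k x 3 sample coordinates (same units as vertices).
#' @return matrix of sampled values (NA outside the mesh).
#' @export
probe_field <- function(vertices, cells, field, points) {
  field <- cbind(field)
  out <- matrix(NA_real_, nrow(points), ncol(field))
  a <- vertices[cells[, 1], , drop = FALSE]
  b <- vertices[cells[, 2], , drop = FALSE]
  cc <- vertices[cells[, 3], , drop = FALSE]
  d <- vertices[cells[, 4], , drop = FALSE]
  lo <- pmin(pmin(a, b), pmin(cc, d))
  hi <- pmax(pmax(a, b), pmax(cc, d))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    cand <- which(lo[, 1] <= p[1] & hi[, 1] >= p[1] &
                    lo[, 2] <= p[2] & hi[, 2] >= p[2] &
                    lo[, 3] <= p[3] & hi[, 3] >= p[3])
    for (e in cand) {
      M <- t(vertices[cells[e, 2:4], , drop = FALSE]) - vertices[cells[e, 1], ]
      lam <- try(solve(M, p - vertices[cells[e, 1], ]), silent = TRUE)
      if (inherits(lam, "try-error")) next
      l <- c(1 - sum(lam), lam)
      if (all(l >= -1e-9)) {
        out[i, ] <- colSums(field[cells[e, ], , drop = FALSE] * l)
        break
      }
    }
  }
  out
}

#' Compare rigid and compliant result bundles
#'
#' Reports the sign-pattern diagnostics of the benchmark: relative change
#' in peak bulge-averaged WSS, the delay between peak swirl and peak inflow
#' for both modes, the outlet-pressure lag after the inflow peak, the neck
#' vertical-velocity profile for both modes and the TAWSS/OSI difference
#' maps.
#'
#' @param bundle_rigid,bundle_compliant result bundles on the same geometry
#'   and waveform.
#' @return a comparison report list.
#' @export
compare_modes <- function(bundle_rigid, bundle_compliant) {
  br <- bundle_rigid; bc <- bundle_compliant
  if (length(br$times) != length(bc$times) ||
      max(abs(br$times - bc$times)) > 1e-12)
    stop("incompatible bundles: different metric sampling")
  peak_r <- max(br$bulge_wss); peak_c <- max(bc$bulge_wss)
  delay_r <- peak_delay(br$swirl, br$inflow, br$times)
  delay_c <- peak_delay(bc$swirl, bc$inflow, bc$times)
  p_lag_c <- peak_delay(bc$p_out, bc$inflow, bc$times)
  p_lag_r <- peak_delay(br$p_out, br$inflow, br$times)
  # neck line probe at systole: v_y along x at the cut-plane height, z = 0
  cut <- br$config$geometry$bulge_cut_height
  xr <- seq(-3, 3, by = 0.1)
  pts <- cbind(xr, cut * 1e-3, 0)
  pts[, 1] <- pts[, 1] * 1e-3
  isys_r <- which.max(br$inflow); isys_c <- which.max(bc$inflow)
  vy_r <- probe_field(br$vcoords[[isys_r]], br$cells,
                      br$vfield[[isys_r]][, 2], pts)[, 1]
  vy_c <- probe_field(bc$vcoords[[isys_c]], bc$cells,
                      bc$vfield[[isys_c]][, 2], pts)[, 1]
  diffm <- field_difference(list(TAWSS = br$TAWSS, OSI = br$OSI),
                            list(TAWSS = bc$TAWSS, OSI = bc$OSI))
  list(peak_bulge_wss = c(rigid = peak_r, compliant = peak_c),
       peak_bulge_wss_rel_change = (peak_r - peak_c) / peak_r,
       swirl_delay_ms = c(rigid = delay_r, compliant = delay_c),
       pressure_lag_ms = c(rigid = p_lag_r, compliant = p_lag_c),
       neck_profile = data.frame(x = xr, vy_rigid = vy_r,
                                 vy_compliant = vy_c),
       difference_maps = diffm)
}
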