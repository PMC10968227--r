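# Inflow waveform construction/calibration, parabolic inlet profile,
# resistance outlet model and solid constraints.
#
# Unit conventions: times in s, flows in mL/s, pressures in kPa at this
# module's surface; velocities in m/s (SI) since they feed the solvers.

MMHG_PER_KPA <- 7.50061683

# Analytic ICA-like pulse shape on the unit cycle: baseline + systolic peak
# + dicrotic bump.  The amplitude of the systolic Gaussian was calibrated
# once so the unit-mean shape has a peak factor of 1.63, which puts the peak
# parent-vessel Reynolds number at ~520 and keeps the resistance-outlet
# pressure between 0 and 40 mmHg for a 4 mL/s mean flow.
ica_pulse_shape <- function(tt) {
  0.75 + 0.7123125 * exp(-((tt - 0.15) / 0.08)^2) +
    0.22 * exp(-((tt - 0.45) / 0.12)^2)
}

#' Build and calibrate the pulsatile inflow waveform
#'
#' The waveform is a ramped periodic pulse: zero at t = 0, growing linearly
#' over \code{ramp} seconds to the start of the first cardiac cycle, then
#' periodic with period \code{T}.  The shape (unit-mean samples over one
#' cycle, linearly interpolated) is scaled so that the cycle-averaged
#' volumetric flow of the parabolic inlet profile equals
#' \code{target_mean_flow} exactly: for a parabolic profile the mean inlet
#' velocity is half the centreline value, so the centreline scale is
#' \code{2 Q / A}.
#'
#' @param shape_spec either \code{NULL} (the built-in ICA-like pulse), a
#'   function of normalized cycle time on [0,1), or a numeric vector of
#'   positive samples over one cycle.
#' @param target_mean_flow cycle-mean volumetric flow in mL/s (default 4).
#' @param inlet_area inlet disc area in mm^2 (default for a 4 mm diameter).
#' @param period cardiac period in s (default 0.8).
#' @param ramp linear start-up ramp duration in s (default 0.2).
#' @param n_samples shape sample count.
#' @return an object of class \code{waveform}.
#' @export
build_waveform <- function(shape_spec = NULL, target_mean_flow = 4,
                           inlet_area = pi * 2^2, period = 0.8, ramp = 0.2,
                           n_samples = 2048L) {
  if (target_mean_flow <= 0) stop("target_mean_flow must be positive")
  tt <- (seq_len(n_samples) - 1L) / n_samples
  s <- if (is.null(shape_spec)) ica_pulse_shape(tt)
       else if (is.function(shape_spec)) shape_spec(tt)
       else {
         ss <- as.numeric(shape_spec)
         approx(x = (seq_along(ss) - 1L) / length(ss), y = ss, xout = tt,
                method = "linear", rule = 2)$y
       }
  if (any(!is.finite(s)) || any(s <= 0))
    stop("shape samples must be positive (reverse inlet flow unsupported)")
  s <- s / mean(s)  # exact unit mean of the periodic linear interpolant
  A_m2 <- inlet_area * 1e-6            # mm^2 -> m^2
  Q_m3 <- target_mean_flow * 1e-6      # mL/s -> m^3/s
  scale <- 2 * Q_m3 / A_m2             # centreline velocity multiplier, m/s
  structure(list(period = period, ramp = ramp, shape = s, scale = scale,
                 target_mean_flow = target_mean_flow,
                 inlet_area = inlet_area),
            class = "waveform")
}

# periodic linear interpolation of the unit-mean shape at cycle phase u=[0,1)
shape_interp <- function(wf, u) {
  n <- length(wf$shape)
  u <- u %% 1
  i <- floor(u * n)
  f <- u * n - i
  i0 <- (i %% n) + 1L
  i1 <- (i0 %% n) + 1L
  (1 - f) * wf$shape[i0] + f * wf$shape[i1]
}

#' Evaluate the centreline inlet velocity V(t)
#'
#' @param wf a \code{\link{build_waveform}} object.
#' @param t time(s) in seconds.
#' @return centreline velocity in m/s (zero at t = 0, linear ramp, then
#'   periodic).
#' @export
waveform_eval <- function(wf, t) {
  v_per <- wf$scale * shape_interp(wf, (t - wf$ramp) / wf$period)
  ramp_f <- pmin(pmax(t / wf$ramp, 0), 1)
  ifelse(t < wf$ramp, ramp_f * wf$scale * shape_interp(wf, 0), v_per)
}

#' Instantaneous inlet volumetric flow
#' @param wf a waveform.
#' @param t time(s), s.
#' @return flow in mL/s (parabolic profile: mean velocity is half the
#'   centreline value).
#' @export
waveform_flow <- function(wf, t) {
  waveform_eval(wf, t) / 2 * (wf$inlet_area * 1e-6) * 1e6
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: T = %g s, ramp = %g s, mean flow = %g mL/s, peak factor = %.3f\n",
              x$period, x$ramp, x$target_mean_flow, max(x$shape)))
  invisible(x)
}

#' Parabolic inlet velocity profile
#'
#' Evaluates the prescribed inlet velocity at points of the inlet disc:
#' \code{v = V(t) (1 - (r/r_in)^2) e_y}, where r is the in-plane distance to
#' the disc centre (the centreline puncture point).
#'
#' @param x n x 3 matrix of points on the inlet disc, mm.
#' @param t time, s.
#' @param wf a \code{\link{build_waveform}} object.
#' @param geom a \code{\link{case_geometry_params}} object (disc centre at
#'   (-torus_major_radius, 0, 0)) or a list with \code{center} (mm) giving
#'   the disc centre directly.
#' @return n x 3 matrix of velocities in m/s (directed along +y).
#' @export
inlet_velocity <- function(x, t, wf, geom) {
  x <- rbind(x)
  center <- if (!is.null(geom$center)) geom$center
            else c(-geom$torus_major_radius, 0, 0)
  r_in <- if (!is.null(geom$radius)) geom$radius else geom$inlet_diameter / 2
  dx <- sweep(x[, c(1, 3), drop = FALSE], 2, center[c(1, 3)])
  r2 <- rowSums(dx^2) / r_in^2
  if (any(r2 > 1 + 1e-9)) stop("point outside the inlet disc")
  V <- waveform_eval(wf, t)
  cbind(0, V * (1 - pmin(r2, 1)), 0)
}

#' Resistance outlet model
#'
#' @param P0 offset pressure, kPa (default -3.7).
#' @param Rd distal hydraulic resistance, kPa s/mL (default 1.31).
#' @return an object of class \code{outlet_model}.
#' @export
outlet_model <- function(P0 = -3.7, Rd = 1.31) {
  if (Rd <= 0) stop("Rd must be positive")
  structure(list(P0 = P0, Rd = Rd), class = "outlet_model")
}

#' Outlet pressure from the instantaneous outflow rate
#'
#' \code{P = P0 + Rd Q}: the downstream vasculature is lumped into a single
#' hydraulic resistance; the result is applied as a uniform normal traction
#' \code{-P n} on the outlet disc.
#'
#' @param Q_out instantaneous outlet flow, mL/s (positive out of the
#'   domain, i.e. along -y at the outlet disc).
#' @param model an \code{\link{outlet_model}}.
#' @return pressure in kPa.
#' @export
outlet_pressure <- function(Q_out, model = outlet_model()) {
  model$P0 + model$Rd * Q_out
}

#' Flow summary statistics of a calibrated waveform
#'
#' Peak Reynolds number based on the inlet diameter and section-mean
#' velocity, and the Womersley number
#' \code{Wo = (D/2) sqrt(2 pi rho / (T mu))}.
#'
#' @param wf a calibrated \code{\link{build_waveform}} object.
#' @param fluid a \code{\link{fluid_params}} object.
#' @param geom a \code{\link{case_geometry_params}} object.
#' @return list with mean/peak flow (mL/s), \code{Re_peak} and \code{Wo}.
#' @export
waveform_stats <- function(wf, fluid = fluid_params(),
                           geom = case_geometry_params()) {
  D <- geom$inlet_diameter * 1e-3
  A <- wf$inlet_area * 1e-6
  Q_mean <- wf$target_mean_flow
  Q_peak <- Q_mean * max(wf$shape)
  Re_peak <- fluid$rho * (Q_peak * 1e-6) * D / (fluid$mu * A)
  Wo <- (D / 2) * sqrt(2 * pi * fluid$rho / (wf$period * fluid$mu))
  list(mean_flow = Q_mean, peak_flow = Q_peak, Re_peak = Re_peak, Wo = Wo)
}

#' Solid kinematic constraints of the benchmark
#'
#' Nodes of the solid mesh on the inflow/outflow plane y = 0 are fully
#' fixed; the exterior surface is traction-free (no constraint entries).
#'
#' @param mesh a solid \code{\link{tagged_mesh}}.
#' @param tol plane tolerance in mm.
#' @return list with \code{fixed_nodes} (vertex indices clamped to zero
#'   displacement).
#' @export
solid_constraints <- function(mesh, tol = 1e-6) {
  fixed <- which(abs(mesh$vertices[, 2]) < tol)
  if (!length(fixed)) stop("no solid nodes on the y = 0 plane")
  list(fixed_nodes = fixed)
}

#' Export / import a waveform as a two-column CSV (t, V)
#'
#' @param wf a waveform.
#' @param path CSV path.
#' @return the path (write) or a waveform rebuilt from samples (read).
#' @export
waveform_to_csv <- function(wf, path) {
  tt <- wf$ramp + wf$period * (seq_along(wf$shape) - 1L) / length(wf$shape)
  write.csv(data.frame(t = tt, V = wf$scale * wf$shape), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname waveform_to_csv
#' @param target_mean_flow,inlet_area,period,ramp as in
#'   \code{\link{build_waveform}}.
#' @export
waveform_from_csv <- function(path, target_mean_flow = 4,
                              inlet_area = pi * 2^2, period = 0.8,
                              ramp = 0.2) {
  d <- read.csv(path)
  build_waveform(shape_spec = d$V, target_mean_flow = target_mean_flow,
                 inlet_area = inlet_area, period = period, ramp = ramp)
}
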