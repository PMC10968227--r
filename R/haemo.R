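# Post-processing of flow and wall results into the haemodynamic
# quantities of interest: wall shear stress vectors, TAWSS, OSI, the
# bulge-averaged WSS time series, the intrasaccular swirl rate, aneurysm
# volume variation and peak-delay diagnostics.  The metric window is the
# second cardiac cycle, [1.0, 1.8] s, to limit initial transients.

#' Wall shear stress vector
#'
#' Tangential projection of the wall traction:
#' \code{tau = sigma.n - ((sigma.n).n) n}.  Accepts either traction vectors
#' (row-wise) with matching unit normals, or a single 3 x 3 stress tensor.
#'
#' @param traction f x 3 matrix of wall tractions (Pa), or a 3 x 3 Cauchy
#'   stress tensor.
#' @param normal f x 3 matrix of outward unit normals (or length-3 vector).
#' @return f x 3 matrix of wall shear vectors (Pa).
#' @export
wall_shear_vector <- function(traction, normal) {
  if (is.matrix(traction) && nrow(traction) == 3 && ncol(traction) == 3 &&
      length(normal) == 3) {
    traction <- matrix(as.numeric(traction %*% normal), 1, 3)
    normal <- matrix(normal, 1, 3)
  }
  normal <- rbind(normal)
  traction <- rbind(traction)
  nlen <- rownorm(normal)
  if (any(abs(nlen - 1) > 1e-6)) stop("normals must be unit length")
  tn <- rowSums(traction * normal)
  traction - tn * normal
}

# Per-vertex wall sample from a per-face traction evaluation: area-weighted
# face-to-vertex averaging of the shear vector, vertex normals, and vertex
# area weights.  `trc` is the result of fluid_traction().
wall_vertex_shear <- function(trc, n_vertices) {
  tau_f <- wall_shear_vector(trc$traction, trc$normal)
  w <- trc$area / 3
  tau_v <- matrix(0, n_vertices, 3)
  wsum <- numeric(n_vertices)
  for (vv in 1:3) {
    acc <- rowsum(cbind(tau_f * w, w), trc$faces[, vv])
    ids <- as.integer(rownames(acc))
    tau_v[ids, ] <- tau_v[ids, ] + acc[, 1:3]
    wsum[ids] <- wsum[ids] + acc[, 4]
  }
  used <- wsum > 0
  tau_v[used, ] <- tau_v[used, ] / wsum[used]
  list(tau = tau_v, varea = wsum, vertices = which(used))
}

#' Wall shear time series container
#'
#' @param times sample times, s.
#' @param tau nt x nv x 3 array of per-vertex shear vectors, Pa.
#' @param vertices vertex ids of the wall surface.
#' @param varea per-vertex area weights, m^2.
#' @param normals per-vertex outward unit normals.
#' @param coords nv x 3 vertex coordinates, mm (reference configuration).
#' @return an object of class \code{wall_series}.
#' @export
wall_series <- function(times, tau, vertices, varea, normals, coords) {
  stopifnot(dim(tau)[1] == length(times), dim(tau)[2] == length(vertices))
  structure(list(times = times, tau = tau, vertices = vertices,
                 varea = varea, normals = normals, coords = coords),
            class = "wall_series")
}

trapz_w <- function(t) {
  nt <- length(t)
  w <- numeric(nt)
  w[1] <- (t[2] - t[1]) / 2
  w[nt] <- (t[nt] - t[nt - 1]) / 2
  if (nt > 2) w[2:(nt - 1)] <- (t[3:nt] - t[1:(nt - 2)]) / 2
  w
}

#' Oscillatory shear index
#'
#' \code{OSI = 1/2 (1 - ||int tau dt|| / int ||tau|| dt)} per vertex over
#' the sampled window (trapezoidal integration); defined as 0 where the
#' shear vanishes identically.
#'
#' @param series a \code{\link{wall_series}}.
#' @return per-vertex OSI values in [0, 0.5].
#' @export
osi <- function(series) {
  if (length(series$times) < 2) stop("need at least 2 samples")
  w <- trapz_w(series$times)
  nt <- length(series$times)
  nv <- dim(series$tau)[2]
  comp <- function(k) matrix(series$tau[, , k], nt, nv)
  mean_vec <- matrix(0, nv, 3)
  for (k in 1:3) mean_vec[, k] <- colSums(comp(k) * w)
  num <- rownorm(mean_vec)
  den <- colSums(sqrt(comp(1)^2 + comp(2)^2 + comp(3)^2) * w)
  out <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(out, 0), 0.5)
}

#' Time-averaged wall shear stress
#'
#' \code{TAWSS = (1/T) int ||tau|| dt} per vertex over the sampled window.
#'
#' @param series a \code{\link{wall_series}}.
#' @return per-vertex TAWSS, Pa.
#' @export
tawss <- function(series) {
  w <- trapz_w(series$times)
  nt <- length(series$times)
  nv <- dim(series$tau)[2]
  comp <- function(k) matrix(series$tau[, , k], nt, nv)
  Tlen <- series$times[nt] - series$times[1]
  colSums(sqrt(comp(1)^2 + comp(2)^2 + comp(3)^2) * w) / Tlen
}

#' Bulge-averaged WSS magnitude time series
#'
#' Area-weighted spatial mean of \code{||tau||} over the bulge surface
#' (vertices above the cut height) at each stored time.
#'
#' @param series a \code{\link{wall_series}}.
#' @param cut_height bulge cut plane, mm (default 8).
#' @return numeric vector over \code{series$times}, Pa.
#' @export
bulge_avg_wss <- function(series, cut_height = 8) {
  sel <- series$coords[, 2] > cut_height
  if (!any(sel)) stop("empty bulge region above y = ", cut_height)
  w <- series$varea[sel]
  mag <- sqrt(series$tau[, sel, 1, drop = FALSE]^2 +
                series$tau[, sel, 2, drop = FALSE]^2 +
                series$tau[, sel, 3, drop = FALSE]^2)[, , 1]
  as.numeric(mag %*% w) / sum(w)
}

#' Intrasaccular swirl rate
#'
#' Upward-going flow rate through the horizontal plane crossing the
#' aneurysm centre: the integral of \code{max(v_y, 0)} over the
#' intersection of the plane with the (deformed) lumen.
#'
#' @param vertices current lumen vertex coordinates, m.
#' @param cells lumen cells.
#' @param v nodal velocity matrix, m/s.
#' @param plane_height plane height, mm (default 10).
#' @param net logical: if TRUE return the signed net flux instead of the
#'   positive part.
#' @return flow in mL/s.
#' @export
swirl_rate <- function(vertices, cells, v, plane_height = 10, net = FALSE) {
  y0 <- plane_height * 1e-3
  if (max(vertices[, 2]) <= y0 || min(vertices[, 2]) >= y0)
    stop("plane misses the lumen")
  q <- fem_plane_positive_flux(vertices, cells, v[, 2], y0)
  if (net) q <- q - fem_plane_positive_flux(vertices, cells, -v[, 2], y0)
  q * 1e6
}

#' Aneurysm volume variation
#'
#' Lumen volume above the cut plane, computed exactly per tetrahedron on
#' the deformed configuration, relative to a diastolic reference volume.
#'
#' @param vertices current lumen vertex coordinates, m.
#' @param cells lumen cells.
#' @param reference_volume diastolic reference volume, mm^3.
#' @param cut_height cut plane, mm (default 8).
#' @return list with \code{volume} (mm^3), \code{delta} (mm^3) and
#'   \code{percent}.
#' @export
aneurysm_volume_variation <- function(vertices, cells, reference_volume,
                                      cut_height = 8) {
  geo <- fem_p1_geometry(vertices, cells)
  vol <- fem_volume_above_plane(vertices, cells, geo$vol,
                                cut_height * 1e-3) * 1e9
  list(volume = vol, delta = vol - reference_volume,
       percent = 100 * (vol - reference_volume) / reference_volume)
}

#' Peak-to-peak time delay between two series
#'
#' \code{t(argmax a) - t(argmax b)} with parabolic sub-sample refinement of
#' both peaks.
#'
#' @param series_a,series_b numeric vectors on a common time grid.
#' @param times the time grid, s.
#' @return delay in ms.
#' @export
peak_delay <- function(series_a, series_b, times) {
  (peak_time(series_a, times) - peak_time(series_b, times)) * 1e3
}

peak_time <- function(y, t) {
  if (diff(range(y)) == 0) stop("flat series has no peak")
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(t[i])
  num <- y[i - 1] - y[i + 1]
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (den == 0) return(t[i])
  t[i] + 0.5 * num / den * (t[i + 1] - t[i])
}

#' Per-vertex metric difference maps (rigid - compliant)
#'
#' @param metrics_rigid,metrics_compliant lists with per-vertex
#'   \code{TAWSS} and \code{OSI} fields on the same reference surface.
#' @return list with \code{dTAWSS} and \code{dOSI}.
#' @export
field_difference <- function(metrics_rigid, metrics_compliant) {
  if (length(metrics_rigid$TAWSS) != length(metrics_compliant$TAWSS))
    stop("mismatched surfaces")
  list(dTAWSS = metrics_rigid$TAWSS - metrics_compliant$TAWSS,
       dOSI = metrics_rigid$OSI - metrics_compliant$OSI)
}
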