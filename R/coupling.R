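# Partitioned Dirichlet-to-Neumann coupling of the fluid and solid solvers
# with Aitken dynamic relaxation: the fluid receives the interface velocity
# of the predicted solid displacement (Dirichlet), the solid receives the
# fluid traction (Neumann), and the fixed point of the composed operator is
# found by relaxed sub-iterations; time advances only after the interface
# residual norm drops below tolerance.

#' Coupling configuration
#'
#' @param tol_fsi convergence tolerance on the node-scaled residual norm,
#'   mm (default 1e-5).
#' @param omega0 initial relaxation factor used for the first two
#'   sub-increments (default 0.1).
#' @param max_subiters sub-iteration cap per time step (default 50).
#' @param omega_clamp admissible relaxation-factor interval guarding
#'   against degenerate Aitken spikes.
#' @param residual_scope \code{"full"} (residual over all solid nodes,
#'   default) or \code{"interface"}.
#' @return an object of class \code{coupling_config}.
#' @export
coupling_config <- function(tol_fsi = 1e-5, omega0 = 0.1,
                            max_subiters = 50L,
                            omega_clamp = c(0.01, 2),
                            residual_scope = c("full", "interface")) {
  if (tol_fsi <= 0) stop("tol_fsi must be positive")
  if (omega0 <= 0 || omega0 > 1) stop("omega0 must lie in (0, 1]")
  structure(list(tol_fsi = tol_fsi, omega0 = omega0,
                 max_subiters = as.integer(max_subiters),
                 omega_clamp = omega_clamp,
                 residual_scope = match.arg(residual_scope)),
            class = "coupling_config")
}

#' FSI interface residual
#'
#' \code{r = u_new - u_pred}; its norm is the Euclidean norm scaled by the
#' node count, reported in mm.
#'
#' @param u_new solid displacement returned by the solid solve (n x 3, m).
#' @param u_pred predicted displacement the fluid saw (n x 3, m).
#' @param nodes optional node subset over which the residual is taken.
#' @return list with \code{r} (n x 3, m) and \code{r_norm} (mm).
#' @export
fsi_residual <- function(u_new, u_pred, nodes = NULL) {
  if (!all(dim(u_new) == dim(u_pred)))
    stop("mismatched node sets in FSI residual")
  r <- u_new - u_pred
  rs <- if (is.null(nodes)) r else r[nodes, , drop = FALSE]
  list(r = r, r_norm = sqrt(sum(rs^2)) / nrow(rs) * 1e3)
}

#' Aitken dynamic relaxation factor
#'
#' \code{omega_k = -omega_{k-1} (r_{k-1} . (r_k - r_{k-1})) /
#' ||r_k - r_{k-1}||^2}, clamped to a safe interval.  Valid from the end of
#' the second sub-increment; before that a fixed omega0 is used.
#'
#' @param omega_prev previous relaxation factor.
#' @param r_prev,r_curr successive residual fields (any conforming shape).
#' @param clamp admissible interval.
#' @return list with \code{omega} and \code{degenerate} (TRUE when the
#'   residual difference vanishes, signalling a convergence stall).
#' @export
aitken_omega <- function(omega_prev, r_prev, r_curr,
                         clamp = c(0.01, 2)) {
  dr <- r_curr - r_prev
  den <- sum(dr^2)
  if (den == 0)
    return(list(omega = omega_prev, degenerate = TRUE))
  om <- -omega_prev * sum(r_prev * dr) / den
  list(omega = min(max(om, clamp[1]), clamp[2]), degenerate = FALSE)
}

#' Relaxed update of the interface prediction
#'
#' \code{u_pred_next = u_pred + omega r}.
#'
#' @param u_pred current prediction.
#' @param r residual field.
#' @param omega relaxation factor.
#' @return updated prediction.
#' @export
relax <- function(u_pred, r, omega) {
  if (!all(dim(rbind(u_pred)) == dim(rbind(r)))) stop("shape mismatch")
  u_pred + omega * r
}

#' Linear displacement predictor
#'
#' Extrapolates the converged displacements of the two previous time levels
#' (\code{2 u_t - u_{t-1}}); falls back to the last level with shorter
#' history, and to zero on a cold start.
#'
#' @param u_t,u_t_minus_1 previous converged displacement fields (or NULL).
#' @return initial prediction for the new time level.
#' @export
predict_displacement <- function(u_t = NULL, u_t_minus_1 = NULL) {
  if (is.null(u_t)) return(NULL)
  if (is.null(u_t_minus_1)) return(u_t)
  2 * u_t - u_t_minus_1
}

# vertex map solid -> fluid over the conforming interface (exact coordinate
# match; the solid shell copies the fluid wall vertices bitwise)
match_interface <- function(fl_mesh, sl_mesh, fl_nodes, sl_nodes) {
  key <- function(V) paste(sprintf("%.12e", V[, 1]),
                           sprintf("%.12e", V[, 2]),
                           sprintf("%.12e", V[, 3]))
  kf <- key(fl_mesh$vertices[fl_nodes, , drop = FALSE])
  ks <- key(sl_mesh$vertices[sl_nodes, , drop = FALSE])
  m <- match(ks, kf)
  if (anyNA(m)) stop("non-conforming interface: unmatched vertices")
  list(sl = sl_nodes, fl = fl_nodes[m])
}

#' One coupled FSI time step
#'
#' Fixed-point loop: predict the solid displacement, move the fluid mesh
#' (harmonic extension), solve the fluid with the interface-velocity
#' Dirichlet condition (BDF2 stencil of the predicted displacement),
#' extract the interface traction, solve the solid under that load, form
#' the residual and apply Aitken-relaxed updates until the node-scaled
#' residual norm is below \code{cfg$tol_fsi} (mm).
#'
#' @param fl_setup,sl_setup fluid and solid solver setups over conforming
#'   meshes.
#' @param imap interface vertex map from \code{match_interface}.
#' @param states list with previous states: \code{flow}, \code{flow2},
#'   \code{solid}, \code{solid2} (may be NULL), and mesh displacement
#'   history \code{d1}, \code{d2}.
#' @param t_new,dt new time level and step size, s.
#' @param cfg a \code{\link{coupling_config}}.
#' @return list with converged \code{flow}, \code{solid}, \code{motion} and
#'   an iteration \code{log} (data.frame: k, r_norm, omega).
#' @export
coupled_step <- function(fl_setup, sl_setup, imap, states, t_new, dt,
                         cfg = coupling_config()) {
  n_f <- fl_setup$n
  n_s <- sl_setup$n
  u1 <- if (!is.null(states$solid)) states$solid$u else matrix(0, n_s, 3)
  u2 <- if (!is.null(states$solid2)) states$solid2$u else NULL
  u_pred <- predict_displacement(u1, u2)
  if (is.null(u_pred)) u_pred <- matrix(0, n_s, 3)
  a0 <- if (is.null(states$flow2)) 1 else 1.5
  # solid interface faces mapped into fluid vertex numbering for loads
  sface <- sl_setup$interface_faces
  fl_of_sl <- integer(n_s)
  fl_of_sl[imap$sl] <- imap$fl
  res_nodes <- if (cfg$residual_scope == "interface")
    sl_setup$interface_nodes else NULL
  omega <- cfg$omega0
  r_prev <- NULL
  flow_ws <- NULL; solid_ws <- NULL   # warm starts across sub-iterations
  log_k <- integer(0); log_r <- numeric(0); log_w <- numeric(0)
  out <- NULL
  for (k in seq_len(cfg$max_subiters)) {
    # fluid-side interface displacement and velocity from the prediction
    ifd <- matrix(0, n_f, 3)
    ifd[fl_of_sl[imap$sl], ] <- u_pred[imap$sl, , drop = FALSE]
    motion <- solve_mesh_motion(fl_setup, ifd,
                                d_hist = states[c("d1", "d2")][
                                  !vapply(states[c("d1", "d2")], is.null,
                                          logical(1))], dt)
    Vc <- fl_setup$V + motion$d_mesh
    wall_v <- matrix(0, n_f, 3)
    uin <- u_pred[imap$sl, , drop = FALSE]
    h1 <- u1[imap$sl, , drop = FALSE]
    h2 <- if (!is.null(u2)) u2[imap$sl, , drop = FALSE] else NULL
    wall_v[fl_of_sl[imap$sl], ] <- if (a0 == 1.5 && !is.null(h2))
      (1.5 * uin - 2 * h1 + 0.5 * h2) / dt else (uin - h1) / dt
    flow <- advance_fluid(fl_setup, states$flow, states$flow2, t_new, dt,
                          vertices_current = Vc, motion = motion,
                          wall_velocity = wall_v,
                          picard_tol = 1e-5, max_picard = 2L,
                          v_init = if (!is.null(flow_ws)) flow_ws$v,
                          lin_tol = 1e-6)
    trc <- fluid_traction(flow, fl_setup, "interface",
                          vertices_current = Vc, geo = flow$geo)
    # traction on the solid boundary: sigma . n_s = -(sigma_f . n_f)
    sl_faces <- matrix(match_vertex_rows(trc$faces, fl_of_sl, imap),
                       ncol = 3L)
    f_ext <- surface_load_vector(n_s, sl_faces, -trc$traction, trc$area)
    solid <- advance_solid(sl_setup, states$solid %||% new_solid_state(n_s),
                           states$solid2, f_ext = f_ext, dt = dt,
                           newton_tol = 1e-6, init = solid_ws,
                           lin_tol = 1e-6, error_on_divergence = FALSE)
    flow_ws <- flow
    if (isTRUE(solid$converged)) solid_ws <- solid
    fr <- fsi_residual(solid$u, u_pred, nodes = res_nodes)
    log_k <- c(log_k, k); log_r <- c(log_r, fr$r_norm); log_w <- c(log_w, omega)
    if (fr$r_norm < cfg$tol_fsi && isTRUE(solid$converged)) {
      out <- list(flow = flow, solid = solid, motion = motion)
      break
    }
    if (k >= 2L && !is.null(r_prev)) {
      au <- aitken_omega(omega, r_prev, fr$r, clamp = cfg$omega_clamp)
      if (!au$degenerate) omega <- au$omega
    }
    u_pred <- relax(u_pred, fr$r, omega)
    r_prev <- fr$r
  }
  if (is.null(out))
    stop("coupling did not converge in ", cfg$max_subiters,
         " sub-iterations (last residual ", signif(tail(log_r, 1), 3),
         " mm)")
  out$log <- data.frame(k = log_k, r_norm = log_r, omega = log_w)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# translate fluid interface face vertex ids to solid ids
match_vertex_rows <- function(faces, fl_of_sl, imap) {
  sl_of_fl <- integer(max(imap$fl))
  sl_of_fl[imap$fl] <- imap$sl
  sl_of_fl[faces]
}
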