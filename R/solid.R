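# Mixed displacement-pressure finite-element solver for the hyperelastic
# arterial wall: neo-Hookean deviatoric energy W = mu/2 (I1bar - 3) with the
# Simo-Taylor volumetric law U(J) = kappa/4 (J^2 - 1) - kappa/2 ln J, so
# U'(J) = kappa/2 (J - 1/J).  P1-P1 tetrahedra with a pressure-gradient
# stabilization (tau ~ h^2 / mu), total-Lagrangian internal forces, BDF2
# inertia, Newton iterations with the consistent tangent.

#' Solid material parameters
#'
#' Region-wise engineering constants converted to the shear and bulk moduli
#' used by the constitutive law.  The bulge is ten times softer than the
#' artery.
#'
#' @param E_bulge bulge Young modulus, MPa (default 0.75).
#' @param E_artery artery Young modulus, MPa (default 7.5 = 10 x bulge).
#' @param nu Poisson ratio (default 0.45).
#' @param rho solid density, kg/m^3 (default 1000).
#' @return an object of class \code{solid_params}.
#' @export
solid_params <- function(E_bulge = 0.75, E_artery = 7.5, nu = 0.45,
                         rho = 1000) {
  mb <- material_from_engineering(E_bulge, nu)
  ma <- material_from_engineering(E_artery, nu)
  structure(list(E_bulge = E_bulge, E_artery = E_artery, nu = nu, rho = rho,
                 mu_bulge = mb$mu, kappa_bulge = mb$kappa,
                 mu_artery = ma$mu, kappa_artery = ma$kappa),
            class = "solid_params")
}

#' Convert engineering constants to shear and bulk moduli
#'
#' \code{mu = E / (2 (1 + nu))}, \code{kappa = E / (3 (1 - 2 nu))} (same
#' units as E).
#'
#' @param E Young modulus.
#' @param nu Poisson ratio, must satisfy 0 < nu < 0.5.
#' @return list with \code{mu} and \code{kappa}.
#' @export
material_from_engineering <- function(E, nu) {
  if (E <= 0) stop("E must be positive")
  if (nu <= 0 || nu >= 0.5)
    stop("nu must lie in (0, 0.5): kappa is unbounded at nu = 0.5")
  if (nu > 0.49999)
    warning("nu extremely close to 0.5; bulk modulus is nearly singular")
  list(mu = E / (2 * (1 + nu)), kappa = E / (3 * (1 - 2 * nu)))
}

#' Neo-Hookean / Simo-Taylor stress evaluation
#'
#' Pointwise constitutive evaluation: volumetric pressure-like stress
#' \code{ps = U'(J) = kappa/2 (J - 1/J)} and deviatoric Cauchy stress
#' \code{dev_sigma = mu J^(-5/3) dev(F F^T)}; the total Cauchy stress is
#' \code{ps I + dev_sigma}.
#'
#' @param F 3 x 3 deformation gradient with positive determinant.
#' @param mu shear modulus.
#' @param kappa bulk modulus.
#' @return list with \code{ps}, \code{dev_sigma} (3 x 3) and \code{J}.
#' @export
stress_neo_hookean <- function(F, mu, kappa) {
  F <- matrix(F, 3, 3)
  J <- det(F)
  if (J <= 0) stop("kinematic error: det F <= 0")
  B <- F %*% t(F)
  dev_sigma <- mu * J^(-5 / 3) * (B - diag(3) * sum(diag(B)) / 3)
  list(ps = 0.5 * kappa * (J - 1 / J), dev_sigma = dev_sigma, J = J)
}

# Precompute reference geometry, per-element materials and constraints.
solid_setup <- function(mesh, params = solid_params(),
                        constraints = NULL) {
  V0 <- mesh$vertices * 1e-3
  TT <- mesh$cells
  n <- nrow(V0)
  geo <- fem_p1_geometry(V0, TT)
  is_bulge <- mesh$region == "bulge-wall"
  MPA <- 1e6
  mu_e <- ifelse(is_bulge, params$mu_bulge, params$mu_artery) * MPA
  kappa_e <- ifelse(is_bulge, params$kappa_bulge, params$kappa_artery) * MPA
  h_e <- (6 * geo$vol / sqrt(2))^(1 / 3)
  tau_e <- h_e^2 / (4 * mu_e)    # pressure-gradient stabilization
  if (is.null(constraints)) constraints <- solid_constraints(mesh)
  mtr <- fem_assemble_mass(TT, geo$vol)
  M <- triplet_sparse(mtr, n)
  # mass triplets replicated onto the three displacement blocks (for the
  # inertia contribution to the tangent, sharing the stiffness pattern)
  mi <- as.integer(mtr$i); mj <- as.integer(mtr$j); mx <- as.numeric(mtr$x)
  m3 <- list(i = c(mi, mi + n, mi + 2L * n),
             j = c(mj, mj + n, mj + 2L * n),
             x = c(mx, mx, mx))
  int_faces <- if (any(mesh$boundary_tags == "interface"))
    mesh_faces_by_tag(mesh, "interface")
  else matrix(integer(0), 0, 3)
  list(mesh = mesh, V0 = V0, T = TT, n = n, geo = geo, params = params,
       h_min = min(h_e), mu_e = mu_e, kappa_e = kappa_e, tau_e = tau_e,
       M = M, m3 = m3,
       fixed_nodes = constraints$fixed_nodes, interface_faces = int_faces,
       interface_nodes = sort(unique(as.integer(int_faces))),
       cache = new.env(parent = emptyenv()))
}

new_solid_state <- function(n, t = 0) {
  list(u = matrix(0, n, 3), udot = matrix(0, n, 3), ps = numeric(n), t = t)
}

#' Nodal force vector from per-face surface tractions
#'
#' Lumps face tractions (Pa) over face areas (m^2) onto vertices (one third
#' per vertex), returning a stacked (3n) force vector in solver dof order.
#'
#' @param n vertex count of the target mesh.
#' @param faces f x 3 face indices into the target mesh.
#' @param traction f x 3 traction matrix, Pa.
#' @param area face areas, m^2.
#' @return numeric vector of length 3n (N).
#' @export
surface_load_vector <- function(n, faces, traction, area) {
  f <- numeric(3 * n)
  for (i in 1:3) {
    contrib <- traction[, i] * area / 3
    acc <- rowsum(rep(contrib, 3L), as.integer(faces))
    ids <- as.integer(rownames(acc))
    f[(i - 1L) * n + ids] <- acc[, 1]
  }
  f
}

#' Advance the solid state by one time step
#'
#' Newton solution of the mixed u-ps system with BDF2 acceleration
#' (\code{udot} and \code{u} both differenced with the second-order backward
#' formula; BDF1 on the first step) under a given interface load and the
#' benchmark constraints (y = 0 nodes fixed, exterior traction-free).
#'
#' @param setup a \code{solid_setup} structure.
#' @param prev,prev2 previous solid states (\code{prev2 = NULL} on the
#'   first step).
#' @param f_ext external nodal force vector (length 3n, N), e.g. from
#'   \code{\link{surface_load_vector}}.
#' @param dt time-step size, s.
#' @param static logical: drop inertia (quasi-static solve).
#' @param newton_tol absolute tolerance on the load-scaled residual norm.
#' @param max_newton iteration cap.
#' @return a solid state: list(u, udot, ps, t, newton_iters).
#' @export
advance_solid <- function(setup, prev, prev2 = NULL, f_ext = NULL, dt = 1,
                          static = FALSE, newton_tol = 1e-8,
                          max_newton = 25L, init = NULL, lin_tol = 1e-8,
                          error_on_divergence = TRUE) {
  n <- setup$n
  if (is.null(f_ext)) f_ext <- numeric(3 * n)
  rho <- setup$params$rho
  if (is.null(prev2)) { a0 <- 1; hu <- prev$u; hv <- prev$udot }
  else { a0 <- 1.5; hu <- 2 * prev$u - 0.5 * prev2$u
         hv <- 2 * prev$udot - 0.5 * prev2$udot }
  fixed <- setup$fixed_nodes
  dir_dofs <- unique(c(as.integer(outer(fixed, (0:2) * n, `+`)),
                       setup$fixed_dofs))
  u <- if (is.null(init)) prev$u else init$u
  ps <- if (is.null(init)) prev$ps else init$ps
  u[fixed, ] <- 0
  scale <- max(sqrt(sum(f_ext^2)), 1e-8)
  iters <- 0L
  ia <- if (static) 0 else rho * (a0 / dt)^2
  last_du <- NULL; last_step <- 0
  for (k in seq_len(max_newton)) {
    iters <- k
    first <- is.null(setup$cache[["solid"]])
    tr <- tryCatch(
      fem_assemble_solid(setup$V0, setup$T, setup$geo$vol,
                         setup$geo$grad, u, ps, setup$mu_e,
                         setup$kappa_e, setup$tau_e,
                         want_pattern = first),
      error = function(e) e)
    if (inherits(tr, "error")) {
      # an aggressive step inverted an element: back off and stop here
      if (error_on_divergence || is.null(last_du)) stop(tr)
      u <- u - 0.75 * last_step * last_du$u
      ps <- ps - 0.75 * last_step * last_du$ps
      rnorm_scaled <- Inf
      break
    }
    R <- tr$res
    R[1:(3 * n)] <- R[1:(3 * n)] - f_ext
    if (!static) {
      udd <- (a0 * (a0 * u - hu) / dt - hv) / dt   # BDF on udot of BDF on u
      Mu <- rho * as.matrix(setup$M %*% udd)
      R[1:(3 * n)] <- R[1:(3 * n)] + as.numeric(Mu)
    }
    R[dir_dofs] <- 0
    rnorm_scaled <- sqrt(sum(R^2)) / scale
    if (rnorm_scaled < newton_tol && k > 1L) break
    sv <- csr_system_solve(setup$cache, "solid",
                           if (first) c(tr$i, setup$m3$i),
                           if (first) c(tr$j, setup$m3$j),
                           c(tr$x, ia * setup$m3$x),
                           -R, dir_dofs, rep(0, length(dir_dofs)),
                           tol = lin_tol)
    dsol <- sv$x
    du <- matrix(dsol[1:(3 * n)], n, 3)
    # damp oversized Newton steps (guards thin elements against transient
    # overshoot-induced inversion); the cap grows with the iteration count
    # so large genuine responses remain reachable
    cap <- 0.25 * setup$h_min * 2^(min(k, 6L) - 1)
    step <- min(1, cap / max(max(abs(du)), 1e-300))
    u <- u + step * du
    ps <- ps + step * dsol[3 * n + 1:n]
    last_du <- list(u = du, ps = dsol[3 * n + 1:n]); last_step <- step
    # negligible full-step increment: converged without a confirming
    # re-assembly
    if (step == 1 &&
        max(abs(du)) < 1e-6 * max(max(abs(u)), 1e-12)) break
    if (k == max_newton && rnorm_scaled >= newton_tol && error_on_divergence)
      stop("stepping error: solid Newton iterations diverged (residual ",
           signif(rnorm_scaled, 3), ")")
  }
  udot <- if (static) matrix(0, n, 3) else (a0 * u - hu) / dt
  list(u = u, udot = udot, ps = ps, t = prev$t + dt, newton_iters = iters,
       converged = rnorm_scaled < newton_tol ||
         (exists("du") && max(abs(du)) < 1e-6 * max(max(abs(u)), 1e-12)))
}

#' Quasi-static solid solve under a ramped load
#'
#' Ramps the external load in \code{n_ramp} equal increments, solving a
#' static Newton problem at each level (useful for inflation fixtures and
#' the small-strain patch test).
#'
#' @param setup a \code{solid_setup} structure.
#' @param f_ext full external nodal force vector (length 3n, N).
#' @param n_ramp number of load increments.
#' @return the converged solid state at full load.
#' @export
solve_static_solid <- function(setup, f_ext, n_ramp = 3L) {
  st <- new_solid_state(setup$n)
  for (k in seq_len(n_ramp))
    st <- advance_solid(setup, st, prev2 = NULL,
                        f_ext = f_ext * (k / n_ramp), static = TRUE)
  st
}

#' Per-element Cauchy stress of a solid state
#'
#' Returns element-wise Cauchy stress tensors built from the element
#' deformation gradient and the element-mean mixed pressure field.
#'
#' @param setup a \code{solid_setup} structure.
#' @param state a solid state.
#' @return list with \code{sigma} (m x 3 x 3 array), \code{J} (m),
#'   \code{F} (m x 3 x 3 array).
#' @export
solid_cauchy_stress <- function(setup, state) {
  TT <- setup$T
  m <- nrow(TT)
  G <- setup$geo$grad
  sig <- array(0, c(m, 3, 3))
  Fs <- array(0, c(m, 3, 3))
  Jv <- numeric(m)
  for (e in seq_len(m)) {
    F <- diag(3)
    for (a in 1:4) {
      ge <- G[e, 3 * (a - 1) + 1:3]
      F <- F + tcrossprod(state$u[TT[e, a], ], ge)
    }
    J <- det(F)
    B <- F %*% t(F)
    pbar <- mean(state$ps[TT[e, ]])
    mu <- setup$mu_e[e]
    sig[e, , ] <- pbar * diag(3) +
      mu * J^(-5 / 3) * (B - diag(3) * sum(diag(B)) / 3)
    Fs[e, , ] <- F
    Jv[e] <- J
  }
  list(sigma = sig, J = Jv, F = Fs)
}

#' Stored hyperelastic energy of a solid state
#'
#' Integral of \code{U(J) + W(C bar)} over the reference domain.
#'
#' @param setup a \code{solid_setup} structure.
#' @param state a solid state.
#' @return energy in J.
#' @export
solid_stored_energy <- function(setup, state) {
  TT <- setup$T
  G <- setup$geo$grad
  tot <- 0
  for (e in seq_len(nrow(TT))) {
    F <- diag(3)
    for (a in 1:4)
      F <- F + tcrossprod(state$u[TT[e, a], ], G[e, 3 * (a - 1) + 1:3])
    J <- det(F)
    I1b <- J^(-2 / 3) * sum(F * F)
    U <- 0.25 * setup$kappa_e[e] * (J^2 - 1) - 0.5 * setup$kappa_e[e] * log(J)
    W <- 0.5 * setup$mu_e[e] * (I1b - 3)
    tot <- tot + setup$geo$vol[e] * (U + W)
  }
  tot
}
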