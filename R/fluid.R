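# Stabilized finite-element solver for the transient incompressible
# Navier-Stokes equations in an ALE frame: P1-P1 tetrahedra with
# residual-based (VMS/ASGS-type) stabilization -- SUPG + PSPG + grad-div
# with quasi-static subscales and the BDF time-step term in tau_M -- and
# BDF2 time stepping (BDF1 startup).  Convection is Picard-linearized with
# the convective velocity (v - vm).  All solver-internal quantities are SI.

#' Physical parameters of the blood model
#'
#' @param rho fluid density, kg/m^3 (default 1000).
#' @param mu dynamic viscosity, Pa s (default 0.004, Newtonian blood).
#' @param f constant body force per unit volume, N/m^3.
#' @return an object of class \code{fluid_params}.
#' @export
fluid_params <- function(rho = 1000, mu = 0.004, f = c(0, 0, 0)) {
  if (rho <= 0 || mu <= 0) stop("rho and mu must be positive")
  structure(list(rho = rho, mu = mu, f = as.numeric(f)),
            class = "fluid_params")
}

# Precompute the dof/boundary structure of a fluid mesh.  `bcs` carries the
# waveform, outlet model and inlet disc description; NULL entries give
# no-flow boundaries.
fluid_setup <- function(mesh, params = fluid_params(), waveform = NULL,
                        outlet = outlet_model(), gamma_floor = NULL) {
  V <- mesh$vertices * 1e-3   # mm -> m
  TT <- mesh$cells
  n <- nrow(V)
  tags <- mesh$boundary_tags
  bf <- mesh$boundary_faces
  inlet_faces <- bf[tags == "inlet", , drop = FALSE]
  outlet_faces <- bf[tags == "outlet", , drop = FALSE]
  wall_faces <- bf[!(tags %in% c("inlet", "outlet")), , drop = FALSE]
  inlet_nodes <- setdiff(sort(unique(as.integer(inlet_faces))),
                         sort(unique(as.integer(wall_faces))))
  wall_nodes <- sort(unique(as.integer(wall_faces)))
  # inlet disc centre and radius from the mesh itself (works for tube and
  # case R alike): centre = area centroid of the inlet faces
  if (nrow(inlet_faces)) {
    ig <- face_geometry(V, inlet_faces)
    ic <- colSums(ig$centroid * ig$area) / sum(ig$area)
    rin <- max(rownorm(sweep(V[unique(as.integer(inlet_faces)), ,
                               drop = FALSE], 2, ic)))
  } else { ic <- c(0, 0, 0); rin <- NA_real_ }
  # interface distance field for the mesh-motion diffusion coefficient
  int_faces <- bf[tags == "interface", , drop = FALSE]
  gamma <- NULL
  if (nrow(int_faces)) {
    cen <- (V[TT[, 1], ] + V[TT[, 2], ] + V[TT[, 3], ] + V[TT[, 4], ]) / 4
    d <- fem_point_surface_dist(cen, V, int_faces)
    if (is.null(gamma_floor)) gamma_floor <- max(1e-6, min(d[d > 0]))
    gamma <- 1 / pmax(d, gamma_floor)^2
  }
  list(mesh = mesh, V = V, T = TT, n = n, params = params,
       waveform = waveform, outlet = outlet,
       inlet_faces = inlet_faces, outlet_faces = outlet_faces,
       wall_faces = wall_faces, interface_faces = int_faces,
       inlet_nodes = inlet_nodes, wall_nodes = wall_nodes,
       interface_nodes = sort(unique(as.integer(int_faces))),
       inlet_center = ic, inlet_radius = rin, gamma = gamma,
       cache = new.env(parent = emptyenv()))
}

new_flow_state <- function(n, t = 0) {
  list(v = matrix(0, n, 3), p = numeric(n), t = t)
}

# sparse matrix from 0-based triplets
triplet_sparse <- function(tr, nd) {
  Matrix::sparseMatrix(i = as.integer(tr$i) + 1L, j = as.integer(tr$j) + 1L,
                       x = as.numeric(tr$x), dims = c(nd, nd))
}

# Sparse linear solve: ILU(0)-preconditioned BiCGSTAB with a direct-solve
# fallback on (rare) Krylov stagnation.
sparse_solve <- function(A, b, tol = 1e-8, maxit = 800L) {
  Ar <- methods::as(A, "RsparseMatrix")
  res <- csr_solve(Ar@p, Ar@j, Ar@x, b, tol, maxit)
  if (!res$converged) {
    warning("iterative solver stagnated (relres ", signif(res$relres, 2),
            "); falling back to a direct solve")
    return(as.numeric(Matrix::solve(A, b)))
  }
  res$x
}

# Linear-system service for the repeated solves on a fixed mesh topology.
# DOFs are permuted to node-interleaved order (all unknowns of a vertex
# adjacent), the symbolic CSR pattern is built once, and systems are solved
# by GMRES preconditioned with a frozen sparse LU factorization that is
# recomputed only when the iteration count degrades (the matrices drift
# slowly across Picard/Newton iterations, sub-iterations and time steps).
# Optionally also returns the pre-Dirichlet residual A0 x - rhs0
# (consistent boundary reactions).
csr_system_solve <- function(cache, key, ti, tj, tx, rhs, dir_dofs,
                             dir_vals, tol = 1e-8, reaction = FALSE) {
  nd <- length(rhs)
  ck <- cache[[key]]
  if (is.null(ck)) {
    nn <- nd %/% 4L    # blocks of n: 3 vector components + 1 scalar
    prm <- if (nd %% 4L == 0L) {
      d <- 0:(nd - 1L)
      (d %% nn) * 4L + (d %/% nn)         # 0-based old -> new
    } else 0:(nd - 1L)                     # scalar systems: identity
    ipx <- integer(nd); ipx[prm + 1L] <- seq_len(nd)   # new -> old (1-based)
    pat <- csr_pattern(prm[as.integer(ti) + 1L], prm[as.integer(tj) + 1L],
                       nd)
    ck <- list(pat = pat, prm = prm, ipx = ipx,
               rowid = rep.int(seq_len(nd), diff(pat$p)),
               factor = NULL, iters_last = Inf)
    cache[[key]] <- ck
  }
  pat <- ck$pat
  x0 <- csr_fill(pat$map, as.numeric(tx), pat$nnz)
  rhs_p <- rhs[ck$ipx]
  sys <- csr_dirichlet(pat$p, pat$j, x0, rhs_p,
                       ck$prm[as.integer(dir_dofs)] ,
                       as.numeric(dir_vals))
  refactor <- is.null(ck$factor) || ck$iters_last > 12L
  sol <- NULL; iters <- 0L
  if (!refactor) {
    g <- lu_pre_gmres(pat, sys$x, ck$factor, sys$rhs, tol)
    if (g$converged) { sol <- g$x; iters <- g$iters }
    else refactor <- TRUE
  }
  if (refactor) {
    A <- Matrix::sparseMatrix(i = ck$rowid, j = pat$j + 1L, x = sys$x,
                              dims = c(nd, nd))
    f <- Matrix::lu(A)
    # expanded factors for dispatch-free triangular solves
    ck$factor <- list(Lp = f@L@p, Li = f@L@i, Lx = f@L@x,
                      Up = f@U@p, Ui = f@U@i, Ux = f@U@x,
                      pr = f@p, qc = f@q)
    sol <- lu_factor_solve(ck$factor, sys$rhs)
    iters <- 1L
  }
  ck$iters_last <- iters
  cache[[key]] <- ck
  if (isTRUE(getOption("aneufsi.solver_verbose")))
    message(sprintf("  [%s] %s iters %d", key,
                    if (refactor) "refactor" else "gmres", iters))
  out <- list(x = sol[ck$prm + 1L], iters = iters)
  if (reaction)
    out$reaction <- csr_residual(pat$p, pat$j, x0, sol, rhs_p)[ck$prm + 1L]
  out
}

lu_factor_solve <- function(f, b)
  as.numeric(csc_lu_solve(f$Lp, f$Li, f$Lx, f$Up, f$Ui, f$Ux, f$pr, f$qc, b))

# GMRES preconditioned by a frozen sparse LU factor (right preconditioning);
# few iterations expected since the factor tracks the drifting matrix.
lu_pre_gmres <- function(pat, avals, factor, b, tol, restart = 30L,
                         maxit = 60L) {
  n <- length(b)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = numeric(n), converged = TRUE, iters = 0L))
  x <- numeric(n)
  total <- 0L
  repeat {
    r <- b - as.numeric(csr_apply(pat$p, pat$j, avals, x))
    beta <- sqrt(sum(r^2))
    if (beta / bnorm < tol)
      return(list(x = x, converged = TRUE, iters = total))
    if (total >= maxit) return(list(x = x, converged = FALSE, iters = total))
    m <- restart
    V <- matrix(0, n, m + 1L)
    H <- matrix(0, m + 1L, m)
    cs <- numeric(m); sn <- numeric(m)
    s <- numeric(m + 1L); s[1] <- beta
    V[, 1] <- r / beta
    i <- 0L
    while (i < m && total < maxit) {
      i <- i + 1L; total <- total + 1L
      z <- lu_factor_solve(factor, V[, i])
      w <- as.numeric(csr_apply(pat$p, pat$j, avals, z))
      for (k in seq_len(i)) {
        H[k, i] <- sum(w * V[, k])
        w <- w - H[k, i] * V[, k]
      }
      H[i + 1L, i] <- sqrt(sum(w^2))
      if (H[i + 1L, i] > 0) V[, i + 1L] <- w / H[i + 1L, i]
      for (k in seq_len(i - 1L)) {
        t1 <- cs[k] * H[k, i] + sn[k] * H[k + 1L, i]
        H[k + 1L, i] <- -sn[k] * H[k, i] + cs[k] * H[k + 1L, i]
        H[k, i] <- t1
      }
      d <- sqrt(H[i, i]^2 + H[i + 1L, i]^2)
      cs[i] <- H[i, i] / d; sn[i] <- H[i + 1L, i] / d
      H[i, i] <- d; H[i + 1L, i] <- 0
      s[i + 1L] <- -sn[i] * s[i]; s[i] <- cs[i] * s[i]
      if (abs(s[i + 1L]) / bnorm < tol) break
    }
    y <- backsolve(H[seq_len(i), seq_len(i), drop = FALSE],
                   s[seq_len(i)])
    x <- x + lu_factor_solve(factor,
                             as.numeric(V[, seq_len(i), drop = FALSE] %*% y))
  }
}

# impose Dirichlet values: rows/cols eliminated symmetrically
apply_dirichlet <- function(A, rhs, dofs, vals) {
  if (!length(dofs)) return(list(A = A, rhs = rhs))
  dofs <- as.integer(dofs)
  rhs <- rhs - as.numeric(A[, dofs, drop = FALSE] %*% vals)
  A[dofs, ] <- 0
  A[, dofs] <- 0
  A <- A + Matrix::sparseMatrix(i = dofs, j = dofs, x = 1, dims = dim(A))
  rhs[dofs] <- vals
  list(A = A, rhs = rhs)
}

#' Advance the fluid state by one time step
#'
#' Solves the stabilized weak form of the incompressible Navier-Stokes
#' equations with BDF2 (BDF1 on the first step), Picard iterations on the
#' convective term, strongly enforced inlet/wall Dirichlet data and the
#' resistance outlet applied weakly as a normal traction \code{-P n} with
#' \code{P = P0 + Rd Q_out} updated within the Picard loop.
#'
#' @param setup a \code{fluid_setup} structure.
#' @param prev,prev2 previous flow states (\code{prev2 = NULL} on the first
#'   step).
#' @param t_new new time level, s.
#' @param dt time-step size, s.
#' @param vertices_current optional current (deformed) vertex coordinates in
#'   m; defaults to the reference coordinates.
#' @param motion optional mesh-motion structure (fields \code{vm},
#'   \code{d_mesh}, m/s and m) for ALE runs.
#' @param wall_velocity optional n x 3 matrix of prescribed wall/interface
#'   velocities (m/s); defaults to no-slip.
#' @param picard_tol,max_picard nonlinear tolerance (relative velocity
#'   increment) and iteration cap.
#' @return a flow state: list(v, p, t, picard_iters, Q_in, Q_out, P_out).
#' @export
advance_fluid <- function(setup, prev, prev2 = NULL, t_new, dt,
                          vertices_current = NULL, motion = NULL,
                          wall_velocity = NULL, fbody = NULL,
                          picard_tol = 1e-6, max_picard = 20L,
                          v_init = NULL, lin_tol = 1e-8) {
  if (dt <= 0) stop("dt must be positive")
  n <- setup$n
  V <- if (is.null(vertices_current)) setup$V else vertices_current
  geo <- fem_p1_geometry(V, setup$T)
  if (any(geo$vol <= 0))
    stop("stepping error: inverted cell in the fluid mesh (try a smaller dt)")
  prm <- setup$params
  if (is.null(fbody)) fbody <- prm$f
  if (is.null(prev2)) { a0 <- 1; hist <- prev$v }
  else { a0 <- 1.5; hist <- 2 * prev$v - 0.5 * prev2$v }
  vm <- if (is.null(motion)) matrix(0, n, 3) else motion$vm
  # Dirichlet data
  g_in <- matrix(0, length(setup$inlet_nodes), 3)
  if (!is.null(setup$waveform) && length(setup$inlet_nodes))
    g_in <- inlet_velocity(setup$mesh$vertices[setup$inlet_nodes, , drop = FALSE],
                           t_new, setup$waveform,
                           list(center = setup$inlet_center * 1e3,
                                radius = setup$inlet_radius * 1e3))
  g_wall <- matrix(0, length(setup$wall_nodes), 3)
  if (!is.null(wall_velocity))
    g_wall <- wall_velocity[setup$wall_nodes, , drop = FALSE]
  dir_dofs <- c(outer(setup$inlet_nodes, (0:2) * n, `+`),
                outer(setup$wall_nodes, (0:2) * n, `+`))
  dir_vals <- c(g_in, g_wall)
  out_fg <- if (nrow(setup$outlet_faces))
    face_geometry(V, setup$outlet_faces) else NULL

  v_pic <- if (is.null(v_init)) prev$v else v_init
  v_pic[setup$wall_nodes, ] <- g_wall
  v_pic[setup$inlet_nodes, ] <- g_in
  P_out <- NA_real_; Q_out <- NA_real_
  iters <- 0L
  reaction <- NULL
  # resistance outlet, implicit: traction -P n with P = P0 + Rd (w . v),
  # where w is the discrete outward-flux functional of the outlet disc.
  # Moving the Rd part to the matrix (rank-one term Rd w w^T) keeps the
  # pressure-flow feedback unconditionally stable.
  w_tri <- NULL
  if (!is.null(out_fg)) {
    w <- numeric(3L * n)
    for (kk in 1:3) {
      acc <- rowsum(rep(out_fg$normal[, kk] * out_fg$area / 3, 3L),
                    as.integer(setup$outlet_faces))
      ids <- as.integer(rownames(acc))
      w[(kk - 1L) * n + ids] <- acc[, 1]
    }
    wdof <- which(w != 0)
    Rd_SI <- setup$outlet$Rd * 1e3 / 1e-6      # kPa/(mL/s) -> Pa/(m^3/s)
    P0_SI <- setup$outlet$P0 * 1e3
    w_tri <- list(i = rep(wdof - 1L, each = length(wdof)),
                  j = rep(wdof - 1L, times = length(wdof)),
                  x = Rd_SI * as.numeric(outer(w[wdof], w[wdof])),
                  rhs_add = -P0_SI * w, w = w)
  }
  dv_prev <- Inf
  for (k in seq_len(max_picard)) {
    iters <- k
    first <- is.null(setup$cache[["ns"]])
    tr <- fem_assemble_ns(V, setup$T, geo$vol, geo$grad, v_pic, vm, hist,
                          prm$rho, prm$mu, a0 / dt, 1 / dt, fbody,
                          want_pattern = first)
    rhs <- tr$rhs
    if (!is.null(w_tri)) {
      ti <- if (first) c(tr$i, w_tri$i)
      tj <- if (first) c(tr$j, w_tri$j)
      tx <- c(tr$x, w_tri$x)
      rhs <- rhs + c(w_tri$rhs_add, numeric(n))
    } else {
      ti <- if (first) tr$i
      tj <- if (first) tr$j
      tx <- tr$x
    }
    sv <- csr_system_solve(setup$cache, "ns", ti, tj, tx, rhs,
                           dir_dofs, dir_vals, tol = lin_tol,
                           reaction = TRUE)
    sol <- sv$x
    reaction <- sv$reaction
    v_new <- matrix(sol[1:(3 * n)], n, 3)
    dv <- sqrt(sum((v_new - v_pic)^2))
    nv <- max(sqrt(sum(v_new^2)), 1e-30)
    v_pic <- v_new
    if (dv / nv < picard_tol) break
    # plateau at the linear-solver noise floor: stop once the increment no
    # longer contracts
    if (k >= 3L && dv > 0.8 * dv_prev) {
      if (dv / nv > 1e-2)
        warning("Picard iterations stalled (", signif(dv / nv, 3), ")")
      break
    }
    dv_prev <- dv
  }
  if (iters == max_picard && dv / nv >= picard_tol && dv / nv > 1e-2)
    warning("Picard iterations did not reach tolerance (", signif(dv / nv, 3), ")")
  Q_in <- if (nrow(setup$inlet_faces))
    surface_flux(V, setup$inlet_faces, v_pic) * 1e6 else NA_real_
  if (!is.null(w_tri)) {
    Q_out <- sum(w_tri$w * as.numeric(v_pic)) * 1e6
    P_out <- outlet_pressure(Q_out, setup$outlet)
  }
  list(v = v_pic, p = sol[3 * n + 1:n], t = t_new, picard_iters = iters,
       reaction = reaction, geo = geo,
       Q_in = Q_in, Q_out = Q_out, P_out = P_out)
}

# signed outward flux through a face set (m^3/s); fg optional precomputed
surface_flux_faces <- function(V, faces, fg, v) {
  vf <- (v[faces[, 1], , drop = FALSE] + v[faces[, 2], , drop = FALSE] +
           v[faces[, 3], , drop = FALSE]) / 3
  sum(rowSums(vf * fg$normal) * fg$area)
}

#' Signed outward volumetric flux through a face set
#' @param V vertex coordinates (m).
#' @param faces face index matrix (outward oriented).
#' @param v nodal velocity matrix (m/s).
#' @return flux in m^3/s (positive out of the domain).
#' @export
surface_flux <- function(V, faces, v) {
  surface_flux_faces(V, faces, face_geometry(V, faces), v)
}

#' Solve the mesh-motion problem
#'
#' Harmonic extension of the interface displacement into the fluid domain
#' with diffusion coefficient \code{gamma = 1/d^2} (d = distance to the
#' interface, floored at the first-layer thickness), so near-interface
#' boundary-layer cells move almost rigidly.  The mesh velocity \code{vm} is
#' the BDF derivative of the extended displacement, which (the operator
#' being time-independent and linear) coincides with the harmonic extension
#' of the interface velocity.
#'
#' @param setup a \code{fluid_setup} structure (reference configuration).
#' @param interface_disp n x 3 matrix (m) of displacements; only rows of
#'   interface nodes are used.
#' @param d_hist list of up to two previous mesh displacement fields for the
#'   BDF derivative (most recent first).
#' @param dt time-step size, s.
#' @return list(d_mesh, vm): n x 3 displacement (m) and velocity (m/s).
#' @export
solve_mesh_motion <- function(setup, interface_disp, d_hist = list(), dt) {
  n <- setup$n
  if (!length(setup$interface_nodes) || is.null(setup$gamma))
    stop("mesh has no tagged interface")
  geo <- fem_p1_geometry(setup$V, setup$T)
  tr <- fem_assemble_lap(setup$T, geo$vol, geo$grad, setup$gamma)
  bnodes <- sort(unique(as.integer(setup$mesh$boundary_faces)))
  inodes <- setup$interface_nodes
  onodes <- setdiff(bnodes, inodes)
  d_mesh <- matrix(0, n, 3)
  for (k in 1:3) {
    sv <- csr_system_solve(setup$cache, "motion", tr$i, tr$j, tr$x,
                           numeric(n), c(inodes, onodes),
                           c(interface_disp[inodes, k],
                             rep(0, length(onodes))))
    d_mesh[, k] <- sv$x
  }
  vm <- if (length(d_hist) >= 2)
    (1.5 * d_mesh - 2 * d_hist[[1]] + 0.5 * d_hist[[2]]) / dt
  else if (length(d_hist) == 1) (d_mesh - d_hist[[1]]) / dt
  else d_mesh / dt
  Vc <- setup$V + d_mesh
  if (any(fem_p1_geometry(Vc, setup$T)$vol <= 0))
    stop("mesh motion inverts a cell; use a smaller dt")
  list(d_mesh = d_mesh, vm = vm)
}

#' Evaluate the fluid traction on a tagged surface
#'
#' Direct-gradient evaluation of \code{sigma_f . n} per boundary face:
#' velocity gradients from the adjacent cell's P1 interpolant, pressure as
#' the face-mean nodal value, outward unit normal from the fluid.
#'
#' @param state a flow state (fields \code{v}, \code{p}).
#' @param setup a \code{fluid_setup} structure.
#' @param tag boundary tag of the surface (default \code{"interface"}).
#' @param vertices_current optional deformed coordinates (m).
#' @return list with \code{traction} (f x 3, Pa), \code{area} (m^2),
#'   \code{normal}, \code{centroid} (m) and \code{faces}.
#' @export
fluid_traction <- function(state, setup, tag = "interface",
                           vertices_current = NULL, geo = NULL) {
  mesh <- setup$mesh
  if (!any(mesh$boundary_tags == tag)) stop("unknown boundary tag: ", tag)
  sel <- which(mesh$boundary_tags == tag)
  faces <- mesh$boundary_faces[sel, , drop = FALSE]
  V <- if (is.null(vertices_current)) setup$V else vertices_current
  ckey <- paste0("bdcell_", tag)
  bd_cell <- setup$cache[[ckey]]
  if (is.null(bd_cell)) {
    bd_cell <- boundary_face_cells(mesh, sel)
    setup$cache[[ckey]] <- bd_cell
  }
  if (is.null(geo)) geo <- fem_p1_geometry(V, setup$T)
  fg <- face_geometry(V, faces)
  mu <- setup$params$mu
  tr <- matrix(0, nrow(faces), 3)
  Gv <- grad_field(geo, setup$T, state$v, bd_cell)   # list of 3x3 per face? no:
  # Gv[[i]][[j]] = d v_i / d x_j as a vector over faces
  pf <- (state$p[faces[, 1]] + state$p[faces[, 2]] + state$p[faces[, 3]]) / 3
  for (i in 1:3) {
    ti <- -pf * fg$normal[, i]
    for (j in 1:3)
      ti <- ti + mu * (Gv[[i]][[j]] + Gv[[j]][[i]]) * fg$normal[, j]
    tr[, i] <- ti
  }
  list(traction = tr, area = fg$area, normal = fg$normal,
       centroid = fg$centroid, faces = faces)
}

#' Consistent (reaction-based) wall traction per vertex
#'
#' Uses the pre-Dirichlet momentum residual of the converged step (the
#' variationally consistent boundary flux): the nodal reaction force on a
#' wall vertex equals the integral of the traction against its basis
#' function, so vertex traction = reaction / vertex area.  More accurate
#' than direct-gradient recovery on coarse boundary layers.
#'
#' @param state a flow state returned by \code{\link{advance_fluid}} (must
#'   carry \code{reaction}).
#' @param setup the \code{fluid_setup} structure.
#' @param vertices_current optional deformed coordinates (m).
#' @param tag boundary tag of the surface (default \code{"interface"}).
#' @return list with \code{vertices} (ids), \code{tau} (n x 3 wall shear,
#'   Pa; zero off the surface), \code{traction}, \code{varea} (m^2) and
#'   \code{normal} per vertex.
#' @export
wall_vertex_traction <- function(state, setup, vertices_current = NULL,
                                 tag = "interface") {
  if (is.null(state$reaction)) stop("state carries no reaction field")
  V <- if (is.null(vertices_current)) setup$V else vertices_current
  faces <- mesh_faces_by_tag(setup$mesh, tag)
  fg <- face_geometry(V, faces)
  n <- setup$n
  varea <- numeric(n)
  for (vv in 1:3) {
    acc <- rowsum(fg$area / 3, faces[, vv])
    ids <- as.integer(rownames(acc))
    varea[ids] <- varea[ids] + acc[, 1]
  }
  nrm <- vertex_normals(V, faces)
  verts <- which(varea > 0)
  f_nodal <- matrix(state$reaction[1:(3 * n)], n, 3)
  trac <- matrix(0, n, 3)
  trac[verts, ] <- f_nodal[verts, ] / varea[verts]
  tn <- rowSums(trac * nrm)
  tau <- trac - tn * nrm
  list(vertices = verts, tau = tau, traction = trac, varea = varea,
       normal = nrm)
}

# map boundary-face row indices to their adjacent cell
boundary_face_cells <- function(mesh, face_rows) {
  key_all <- facet_key(mesh$boundary_faces[face_rows, , drop = FALSE])
  fc <- tet_facets(mesh$cells)
  key_fc <- facet_key(fc$faces)
  fc$cell[match(key_all, key_fc)]
}

# per-face velocity gradient components from adjacent cells
grad_field <- function(geo, TT, v, cells) {
  G <- geo$grad
  out <- vector("list", 3)
  for (i in 1:3) {
    out[[i]] <- vector("list", 3)
    for (j in 1:3) {
      g <- numeric(length(cells))
      for (a in 1:4)
        g <- g + v[TT[cells, a], i] * G[cells, 3 * (a - 1) + j]
      out[[i]][[j]] <- g
    }
  }
  out
}
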