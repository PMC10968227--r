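test_that("quiescent flow stays quiescent", {
  m <- make_tube_fixture(2, 8, 0.9)
  setup <- aneufsi:::fluid_setup(m, fluid_params(),
                                 outlet = outlet_model(P0 = 0, Rd = 1))
  st <- aneufsi:::new_flow_state(setup$n)
  for (k in 1:3)
    st <- advance_fluid(setup, st, NULL, k * 1e-3, 1e-3)
  expect_lt(max(abs(st$v)), 1e-10)
})

test_that("hydrostatic pressure yields pure normal traction", {
  m <- make_tube_fixture(2, 8, 0.9)
  setup <- aneufsi:::fluid_setup(m, fluid_params())
  st <- aneufsi:::new_flow_state(setup$n)
  st$p <- rep(250, setup$n)   # constant pressure field
  trc <- fluid_traction(st, setup, "interface")
  expect_lt(max(abs(trc$traction + 250 * trc$normal)), 1e-9)
  # closed-surface equilibrium: total force of a constant-pressure field
  bd <- m$boundary_faces
  fg <- aneufsi:::face_geometry(setup$V, bd)
  force <- colSums(-250 * fg$normal * fg$area)
  expect_lt(max(abs(force)), 1e-12)
  expect_error(fluid_traction(st, setup, "no-such-tag"), "unknown")
})

test_that("steady tube flow recovers the Poiseuille solution", {
  r <- poiseuille_result()
  expect_lt(rel_err(r$wss, r$wss_expected), 0.02)
  expect_lt(rel_err(r$centreline, r$centreline_expected), 0.02)
  # mass conservation at convergence (signed outward fluxes)
  expect_lt(abs(r$state$Q_in + r$state$Q_out) / abs(r$state$Q_in), 1e-3)
})

test_that("oscillatory tube flow matches the analytic Womersley series", {
  r <- womersley_result()
  expect_lt(r$l2_rel, 0.03)
})

test_that("mesh motion extends interface displacement harmonically", {
  m <- make_tube_fixture(2, 10, 0.9)
  setup <- aneufsi:::fluid_setup(m, fluid_params())
  n <- setup$n
  # zero interface displacement -> identically zero motion
  mo0 <- solve_mesh_motion(setup, matrix(0, n, 3), list(), 1e-3)
  expect_lt(max(abs(mo0$d_mesh)), 1e-14)
  expect_lt(max(abs(mo0$vm)), 1e-11)
  # uniform radial inflation: interior displacement magnitude decreases
  # monotonically with distance from the interface (binned means)
  rr <- vec_norms(m$vertices[, c(1, 3)])
  ifd <- matrix(0, n, 3)
  wall <- setup$interface_nodes
  ifd[wall, 1] <- 1e-4 * m$vertices[wall, 1] / rr[wall]
  ifd[wall, 3] <- 1e-4 * m$vertices[wall, 3] / rr[wall]
  mo <- solve_mesh_motion(setup, ifd, list(), 1e-3)
  mag <- vec_norms(mo$d_mesh)
  mid <- abs(m$vertices[, 2] - 5) < 2.5
  bins <- cut(rr[mid], breaks = seq(0, 2, by = 0.5))
  mm <- tapply(mag[mid], bins, mean)
  mm <- mm[!is.na(mm)]
  expect_true(all(diff(mm) > 0))   # grows toward the wall
  # boundary values are reproduced
  expect_lt(max(abs(mo$d_mesh[wall, ] - ifd[wall, ])), 1e-12)
})

test_that("free-stream state survives prescribed interior mesh motion", {
  # all boundaries held still, interior mesh nodes displaced: a quiescent
  # state must remain quiescent to solver tolerance
  m <- make_tube_fixture(2, 8, 0.9)
  m$boundary_tags[] <- "interface"    # full Dirichlet control
  setup <- aneufsi:::fluid_setup(m, fluid_params())
  n <- setup$n
  st <- aneufsi:::new_flow_state(n)
  bnodes <- sort(unique(as.integer(m$boundary_faces)))
  interior <- setdiff(seq_len(n), bnodes)
  dt <- 1e-3
  d_mesh <- matrix(0, n, 3)
  rr <- vec_norms(m$vertices[, c(1, 3)])
  # smooth interior bump, zero at all boundaries
  wgt <- (1 - (rr[interior] / 2)^2) *
    sin(pi * m$vertices[interior, 2] / 8)
  d_mesh[interior, 2] <- 5e-5 * wgt
  motion <- list(d_mesh = d_mesh, vm = d_mesh / dt)
  st2 <- advance_fluid(setup, st, NULL, dt, dt,
                       vertices_current = setup$V + d_mesh,
                       motion = motion)
  expect_lt(max(abs(st2$v)), 1e-6)
})

test_that("element divergence decreases under refinement on Poiseuille", {
  div_norm <- function(resolution) {
    m <- make_tube_fixture(2, 5, resolution)
    wf <- build_waveform(shape_spec = function(tt) rep(1, length(tt)),
                         target_mean_flow = 4, inlet_area = pi * 4,
                         ramp = 1e-3)
    setup <- aneufsi:::fluid_setup(m, fluid_params(), waveform = wf,
                                   outlet = outlet_model(P0 = 0, Rd = 1e-12))
    st <- advance_fluid(setup, aneufsi:::new_flow_state(setup$n), NULL,
                        10, 1e6, picard_tol = 1e-5)
    geo <- fem_p1_geometry(setup$V, setup$T)
    dv <- numeric(nrow(setup$T))
    for (a in 1:4)
      for (k in 1:3)
        dv <- dv + st$v[setup$T[, a], k] * geo$grad[, 3 * (a - 1) + k]
    sqrt(sum(geo$vol * dv^2))
  }
  expect_lt(div_norm(1.5), div_norm(0.8))
})
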