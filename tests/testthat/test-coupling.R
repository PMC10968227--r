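test_that("FSI residual norm is the node-scaled Euclidean norm", {
  # single node, displacement difference (3, 4, 0) micrometres
  u_new <- matrix(c(3e-6, 4e-6, 0), 1, 3)
  u_pred <- matrix(0, 1, 3)
  fr <- fsi_residual(u_new, u_pred)
  expect_equal(fr$r_norm, 5e-3)   # 5 um in mm
  # identical fields converge with zero residual
  fr0 <- fsi_residual(u_new, u_new)
  expect_equal(fr0$r_norm, 0)
  expect_equal(max(abs(fr0$r)), 0)
  # homogeneity
  fr2 <- fsi_residual(2 * u_new, 2 * u_pred)
  expect_equal(fr2$r_norm, 2 * fr$r_norm)
  expect_error(fsi_residual(matrix(0, 2, 3), matrix(0, 3, 3)), "mismatch")
})

test_that("Aitken factor follows the secant identity", {
  # scalars: omega_prev = 0.1, r_prev = 1, r_curr = 0.5 -> omega = 0.2
  au <- aitken_omega(0.1, 1, 0.5)
  expect_equal(au$omega, 0.2)
  expect_false(au$degenerate)
  # degenerate branch
  aud <- aitken_omega(0.3, 1, 1)
  expect_true(aud$degenerate)
  expect_equal(aud$omega, 0.3)
  # clamping guards spikes
  auc <- aitken_omega(1, 1, 1 - 1e-9, clamp = c(0.01, 2))
  expect_lte(auc$omega, 2)
})

test_that("relaxation and prediction follow their defining formulas", {
  expect_equal(relax(0, 2, 0.5), 1)
  expect_equal(relax(c(1, 2), c(1, 1), 0), c(1, 2))
  u <- matrix(1:6, 2, 3)
  expect_equal(relax(u, u * 0 + 1, 1), u + 1)
  # predictor: exact for linear-in-time motion, constant for constant
  expect_equal(predict_displacement(u, u), u)
  expect_equal(predict_displacement(3 * u, 2 * u), 4 * u)
  expect_equal(predict_displacement(u, NULL), u)
  expect_null(predict_displacement(NULL))
})

test_that("Aitken solves a linear fixed point in a few sub-iterations", {
  r <- aneufsi:::run_aitken_check(a = -3, b = 4)
  expect_lte(r$iters, 5)   # two omega0 steps + <= 3 accelerated
  expect_equal(r$x, r$fixed_point, tolerance = 1e-9)
  # strictly fewer iterations than fixed under-relaxation
  fixed_iters <- local({
    x <- 0; k <- 0
    while (abs(-3 * x + 4 - x) >= 1e-12 && k < 400) {
      x <- x + 0.1 * (-3 * x + 4 - x); k <- k + 1
    }
    k
  })
  expect_lt(r$iters, fixed_iters)
})

test_that("coupled solver reduces to pure CFD in the rigid limit", {
  r <- rigid_limit_result()
  # interface barely moves
  expect_lt(r$max_u_mm, 1e-4)
  # velocity fields agree in L2 within 0.5%
  expect_lt(r$v_l2_rel, 0.005)
  # converged step satisfied the prescribed interface tolerance
  expect_lt(r$last_r, 1e-5)
  expect_true(is.data.frame(r$log))
})

test_that("an elastic tube propagates a pressure wave downstream", {
  r <- pressure_wave_result()
  pk <- r$peak_pos[r$launched]   # after the inflow pulse crest
  expect_gte(length(pk), 3)
  expect_true(all(diff(pk) >= -1e-9))
  expect_gt(tail(pk, 1), pk[1])
})

test_that("repeated coupled runs are bit-identical", {
  run_once <- function() {
    fl_mesh <- make_tube_fixture(2, 8, 0.8)
    sl_mesh <- make_tube_shell(fl_mesh, 0.25, 1L)
    wf <- build_waveform(shape_spec = function(tt) rep(1, length(tt)),
                         target_mean_flow = 2, inlet_area = pi * 4,
                         ramp = 5e-3)
    fls <- fluid_setup(fl_mesh, fluid_params(), waveform = wf,
                       outlet = outlet_model(P0 = 0, Rd = 0.3))
    tolp <- 1e-6
    fix <- which(abs(sl_mesh$vertices[, 2]) < tolp |
                   abs(sl_mesh$vertices[, 2] - 8) < tolp)
    sls <- aneufsi:::solid_setup(sl_mesh, solid_params(0.75, 0.75),
                                 constraints = list(fixed_nodes = fix))
    imap <- aneufsi:::match_interface(fl_mesh, sl_mesh,
                                      fls$interface_nodes,
                                      sls$interface_nodes)
    st <- list(flow = aneufsi:::new_flow_state(fls$n), flow2 = NULL,
               solid = aneufsi:::new_solid_state(sls$n), solid2 = NULL,
               d1 = NULL, d2 = NULL)
    iters <- integer(0)
    for (k in 1:3) {
      res <- coupled_step(fls, sls, imap, st, k * 1e-3, 1e-3,
                          coupling_config())
      st$flow2 <- st$flow; st$flow <- res$flow
      st$solid2 <- st$solid; st$solid <- res$solid
      st$d2 <- st$d1; st$d1 <- res$motion$d_mesh
      iters <- c(iters, nrow(res$log))
    }
    list(iters = iters, u = st$solid$u, v = st$flow$v)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$iters, r2$iters)
  expect_identical(r1$u, r2$u)
  expect_identical(r1$v, r2$v)
})
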