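test_that("waveform calibration hits the target mean flow exactly", {
  wf <- build_waveform()
  # cycle-mean flow over the second cycle, fine quadrature
  tt <- seq(1.0, 1.8, length.out = 16001)[-16001]
  expect_lt(abs(mean(waveform_flow(wf, tt)) - 4) / 4, 1e-6)
  # shape has unit mean
  expect_lt(abs(mean(wf$shape) - 1), 1e-10)
  # linearity of the calibrated scale in the target
  wf2 <- build_waveform(target_mean_flow = 8)
  expect_equal(wf2$scale, 2 * wf$scale, tolerance = 1e-12)
})

test_that("waveform is ramped, continuous and periodic", {
  wf <- build_waveform()
  # linear growth over the ramp
  expect_equal(waveform_eval(wf, 0), 0)
  expect_equal(waveform_eval(wf, 0.1), 0.5 * waveform_eval(wf, 0.2),
               tolerance = 1e-12)
  # continuity at the ramp end
  expect_lt(abs(waveform_eval(wf, 0.2 - 1e-9) - waveform_eval(wf, 0.2 + 1e-9)),
            1e-5 * wf$scale)
  # periodicity beyond the ramp
  tt <- seq(0.25, 1.0, by = 0.01)
  expect_equal(waveform_eval(wf, tt), waveform_eval(wf, tt + 0.8),
               tolerance = 1e-12)
  # constant shape gives steady flow after the ramp
  wfc <- build_waveform(shape_spec = function(tt) rep(1, length(tt)))
  expect_equal(diff(range(waveform_eval(wfc, seq(0.3, 1.7, by = 0.01)))), 0)
  expect_error(build_waveform(shape_spec = function(tt) tt - 0.5),
               "positive")
})

test_that("parabolic inlet profile has the analytic shape and flux", {
  wf <- build_waveform()
  geom <- case_geometry_params()
  t <- 1.12
  Vt <- waveform_eval(wf, t)
  centre <- c(-geom$torus_major_radius, 0, 0)
  expect_equal(as.numeric(inlet_velocity(rbind(centre), t, wf, geom)[1, 2]),
               Vt)
  rim <- centre + c(2, 0, 0)
  expect_equal(max(abs(inlet_velocity(rbind(rim), t, wf, geom))), 0)
  expect_error(inlet_velocity(rbind(centre + c(2.5, 0, 0)), t, wf, geom),
               "outside")
  # disc integral = V(t) A / 2 (parabolic mean is half the peak)
  nr <- 400
  rr <- (seq_len(nr) - 0.5) / nr * 2
  ring_area <- 2 * pi * rr * (2 / nr)
  vy <- inlet_velocity(cbind(centre[1] + rr, 0, 0), t, wf, geom)[, 2]
  expect_lt(rel_err(sum(vy * ring_area), Vt * pi * 4 / 2), 1e-4)
})

test_that("resistance outlet pressure is the affine law of the flux", {
  m <- outlet_model()
  expect_equal(outlet_pressure(0, m), -3.7)
  expect_equal(outlet_pressure(4, m), -3.7 + 1.31 * 4)
  expect_lt(abs(outlet_pressure(3.7 / 1.31, m)), 1e-12)
})

test_that("outlet pressure stays inside the physiological corridor", {
  wf <- build_waveform()
  tt <- seq(1.0, 1.8, length.out = 8001)
  p_kpa <- outlet_pressure(waveform_flow(wf, tt))
  p_mmhg <- p_kpa * 7.50061683
  expect_gte(min(p_mmhg), 0)
  expect_lte(max(p_mmhg), 40)
})

test_that("flow summary reproduces the parent-vessel dimensionless numbers", {
  st <- waveform_stats(build_waveform())
  expect_equal(round(st$Wo, 1), 2.8)
  expect_gte(st$Re_peak, 500)
  expect_lte(st$Re_peak, 540)
  # Womersley number vanishes in the long-period limit
  stl <- waveform_stats(build_waveform(period = 1e9))
  expect_lt(stl$Wo, 1e-3)
})

test_that("solid constraints fix exactly the inflow/outflow-plane nodes", {
  s <- coarse_tube_shell()
  con <- solid_constraints(s)
  on_plane <- which(abs(s$vertices[, 2]) < 1e-6 |
                      abs(s$vertices[, 2] - 20) < 1e-6)
  # tube shell fixture clamps both end annuli
  fix_both <- which(abs(s$vertices[, 2]) < 1e-6)
  expect_setequal(con$fixed_nodes, fix_both)
  expect_gt(length(con$fixed_nodes), 0)
  shifted <- s
  shifted$vertices[, 2] <- shifted$vertices[, 2] + 5
  expect_error(solid_constraints(shifted), "y = 0")
})

test_that("waveform CSV round trip preserves the calibrated pulse", {
  wf <- build_waveform()
  path <- tempfile(fileext = ".csv")
  waveform_to_csv(wf, path)
  wf2 <- waveform_from_csv(path)
  tt <- seq(0, 1.8, by = 0.01)
  expect_equal(waveform_eval(wf2, tt), waveform_eval(wf, tt),
               tolerance = 1e-6)
})
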