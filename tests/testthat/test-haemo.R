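test_that("wall shear is the tangential part of the traction", {
  # pure pressure has no shear
  sig <- -500 * diag(3)
  expect_lt(max(abs(wall_shear_vector(sig, c(0, 1, 0)))), 1e-12)
  # Newtonian shear flow v = (gdot y, 0, 0) at a wall with normal e_y
  mu <- 0.004; gdot <- 150
  gradv <- matrix(0, 3, 3); gradv[1, 2] <- gdot
  sig <- mu * (gradv + t(gradv))
  tau <- wall_shear_vector(sig, c(0, 1, 0))
  expect_equal(vec_norms(tau), mu * gdot, tolerance = 1e-12)
  # tangency for arbitrary tractions
  set.seed(3)
  tr <- matrix(rnorm(30), 10, 3)
  nn <- rowunit <- tr * 0
  nn <- aneufsi:::rowunit(matrix(rnorm(30), 10, 3))
  tau2 <- wall_shear_vector(tr, nn)
  expect_lt(max(abs(rowSums(tau2 * nn))), 1e-12)
  expect_error(wall_shear_vector(tr, nn * 2), "unit")
})

test_that("OSI attains its limit values exactly", {
  r <- aneufsi:::run_osi_limits_check()
  expect_equal(max(abs(r$osi_constant)), 0)
  expect_equal(max(abs(r$osi_reversing - 0.5)), 0)
  # uniformly rotating shear of constant magnitude -> OSI = 0.5
  times <- seq(1.0, 1.8, length.out = 81)
  ph <- 2 * pi * (times - 1) / 0.8
  tau <- array(0, c(81, 1, 3))
  tau[, 1, 1] <- 2 * cos(ph); tau[, 1, 3] <- 2 * sin(ph)
  ws <- wall_series(times, tau, 1L, 1, NULL, cbind(0, 9, 0))
  expect_equal(osi(ws), 0.5, tolerance = 1e-6)
})

test_that("TAWSS integrates the shear magnitude over the window", {
  times <- seq(1.0, 1.8, length.out = 161)
  tau <- array(0, c(161, 2, 3))
  tau[, 1, 1] <- 2                                   # constant 2 Pa
  tau[, 2, 1] <- 3 * abs(sin(pi * (times - 1) / 0.8)) # half-period bump
  ws <- wall_series(times, tau, 1:2, c(1, 1), NULL, cbind(c(0, 1), 9, 0))
  tw <- tawss(ws)
  expect_equal(tw[1], 2, tolerance = 1e-12)
  expect_equal(tw[2], 3 * 2 / pi, tolerance = 1e-3)   # mean of |sin|
  # triangle inequality: TAWSS >= |time-mean shear vector|
  set.seed(9)
  tau3 <- array(rnorm(161 * 2 * 3), c(161, 2, 3))
  ws3 <- wall_series(times, tau3, 1:2, c(1, 1), NULL, cbind(c(0, 1), 9, 0))
  mean_vec <- apply(tau3, c(2, 3), function(x)
    sum(x * aneufsi:::trapz_w(times))) / 0.8
  expect_true(all(tawss(ws3) >= vec_norms(mean_vec) - 1e-12))
})

test_that("bulge-averaged WSS is the area-weighted spatial mean", {
  times <- c(1.0, 1.4, 1.8)
  tau <- array(0, c(3, 2, 3))
  tau[, 1, 1] <- 1; tau[, 2, 1] <- 3
  ws <- wall_series(times, tau, 1:2, c(2, 2), NULL,
                    cbind(c(0, 1), c(9, 10), 0))   # equal areas, both y > 8
  expect_equal(bulge_avg_wss(ws, 8), rep(2, 3))
  # uniform magnitude c -> constant series c
  tau[, , 1] <- 1.5
  ws2 <- wall_series(times, tau, 1:2, c(2, 5), NULL,
                     cbind(c(0, 1), c(9, 10), 0))
  expect_equal(bulge_avg_wss(ws2, 8), rep(1.5, 3))
  expect_error(bulge_avg_wss(ws2, 99), "empty")
})

test_that("swirl rate integrates the upward-going flux through the plane", {
  m <- make_tube_fixture(2, 20, 1.2)
  V <- m$vertices * 1e-3
  n <- nrow(V)
  A <- sum(aneufsi:::face_geometry(V, mesh_faces_by_tag(m, "inlet"))$area)
  # uniform upward flow c: swirl = c A
  v <- matrix(0, n, 3); v[, 2] <- 0.25
  q <- swirl_rate(V, m$cells, v, plane_height = 10)
  expect_lt(rel_err(q, 0.25 * A * 1e6), 1e-9)
  # antisymmetric profile (vy = x): positive part is half the absolute flux
  v2 <- matrix(0, n, 3); v2[, 2] <- V[, 1]
  qpos <- swirl_rate(V, m$cells, v2, plane_height = 10)
  qneg <- swirl_rate(V, m$cells, -v2, plane_height = 10)
  expect_lt(rel_err(qpos, qneg), 1e-9)
  qnet <- swirl_rate(V, m$cells, v2, plane_height = 10, net = TRUE)
  expect_lt(abs(qnet), 1e-9 * qpos)
  # quiescent flow
  expect_equal(swirl_rate(V, m$cells, v * 0, plane_height = 10), 0)
  expect_error(swirl_rate(V, m$cells, v, plane_height = 50), "misses")
})

test_that("clipped volumes match closed-form cylinder and sphere caps", {
  # cylinder: volume above y0 is exact for the polyhedral mesh
  m <- make_tube_fixture(2, 20, 1)
  V <- m$vertices * 1e-3
  geo <- fem_p1_geometry(V, m$cells)
  vtot <- sum(geo$vol)
  v1 <- fem_volume_above_plane(V, m$cells, geo$vol, 5e-3)
  expect_lt(rel_err(v1, vtot * 15 / 20), 1e-12)
  # sphere cap, compared against the equivalent-volume sphere
  b <- make_ball_mesh(2, subdiv = 16L, layers = 3L)
  Vb <- b$vertices * 1e-3
  geob <- fem_p1_geometry(Vb, b$cells)
  vol <- sum(geob$vol) * 1e9
  a_eff <- (3 * vol / (4 * pi))^(1 / 3)
  y0 <- 0.5
  h <- a_eff - y0
  capx <- pi * h^2 * (3 * a_eff - h) / 3
  capv <- fem_volume_above_plane(Vb, b$cells, geob$vol, y0 * 1e-3) * 1e9
  expect_lt(rel_err(capv, capx), 1e-3)
  # volume-variation bookkeeping: undeformed vs itself is 0%
  av <- aneurysm_volume_variation(Vb, b$cells, capv, cut_height = y0)
  expect_equal(av$percent, 0)
  expect_equal(av$delta, 0)
  # uniform normal inflation by delta << a: dV ~ delta x curved cap area
  del <- 1e-3   # mm
  Vb2 <- Vb * (1 + del / a_eff)      # radial offset ~ delta on the surface
  capv2 <- fem_volume_above_plane(Vb2, b$cells,
                                  fem_p1_geometry(Vb2, b$cells)$vol,
                                  y0 * 1e-3) * 1e9
  cap_area <- 2 * pi * a_eff * h     # curved (lateral) cap area
  expect_lt(rel_err(capv2 - capv, del * cap_area), 0.05)
})

test_that("peak delays are recovered with sub-sample accuracy", {
  tt <- seq(1.0, 1.8, by = 0.002)
  a <- sin(2 * pi * (tt - 1) / 0.8)
  b <- sin(2 * pi * (tt - 1 - 0.016) / 0.8)
  expect_equal(peak_delay(a, a, tt), 0)
  expect_lt(abs(peak_delay(b, a, tt) - 16), 2)   # within one sample
  expect_equal(peak_delay(a, b, tt), -peak_delay(b, a, tt),
               tolerance = 1e-9)
  expect_error(peak_delay(rep(1, length(tt)), a, tt), "flat")
})

test_that("difference maps are antisymmetric and linear", {
  mr <- list(TAWSS = c(1, 2, 3), OSI = c(0.1, 0.2, 0.3))
  mc <- list(TAWSS = c(0.5, 2, 4), OSI = c(0.1, 0.1, 0.4))
  d <- field_difference(mr, mc)
  expect_equal(d$dTAWSS, c(0.5, 0, -1))
  d2 <- field_difference(mc, mr)
  expect_equal(d2$dTAWSS, -d$dTAWSS)
  expect_equal(mean(d$dTAWSS), mean(mr$TAWSS) - mean(mc$TAWSS))
  expect_equal(field_difference(mr, mr)$dOSI, c(0, 0, 0))
  expect_error(field_difference(mr, list(TAWSS = 1:2, OSI = 1:2)),
               "mismatch")
})
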