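test_that("constitutive law reproduces closed-form stresses", {
  mats <- material_from_engineering(0.75, 0.45)
  # stress-free reference
  s0 <- stress_neo_hookean(diag(3), mats$mu, mats$kappa)
  expect_equal(s0$ps, 0)
  expect_equal(max(abs(s0$dev_sigma)), 0)
  # pure dilatation: deviatoric part vanishes, ps = U'(J)
  lam <- 1.1
  s1 <- stress_neo_hookean(lam * diag(3), mats$mu, mats$kappa)
  expect_lt(max(abs(s1$dev_sigma)), 1e-12)
  expect_equal(s1$ps, 0.5 * mats$kappa * (lam^3 - lam^-3), tolerance = 1e-12)
  # simple shear (J = 1): dev_sigma = mu dev(F F^T), trace-free
  gam <- 0.3
  Fs <- diag(3); Fs[1, 2] <- gam
  s2 <- stress_neo_hookean(Fs, mats$mu, mats$kappa)
  B <- Fs %*% t(Fs)
  expect_equal(s2$dev_sigma,
               mats$mu * (B - diag(3) * sum(diag(B)) / 3), tolerance = 1e-12)
  expect_lt(abs(sum(diag(s2$dev_sigma))), 1e-12)
  expect_error(stress_neo_hookean(-diag(3), 1, 1), "det F")
})

test_that("engineering-constant conversion and its guards", {
  m1 <- material_from_engineering(0.75, 0.45)
  expect_equal(m1$mu, 0.75 / 2.9, tolerance = 1e-12)
  expect_equal(m1$kappa, 2.5, tolerance = 1e-12)
  m2 <- material_from_engineering(7.5, 0.45)
  expect_equal(m2$mu, 10 * m1$mu, tolerance = 1e-12)
  expect_equal(m2$kappa, 25, tolerance = 1e-12)
  expect_error(material_from_engineering(1, 0.5), "0.5")
  expect_warning(material_from_engineering(1, 0.499999), "singular")
})

test_that("stress evaluation is objective under rotations", {
  set.seed(42)
  mats <- material_from_engineering(0.75, 0.45)
  F0 <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
  if (det(F0) <= 0) F0 <- diag(3) + 0.05
  s0 <- stress_neo_hookean(F0, mats$mu, mats$kappa)
  for (k in 1:5) {
    R <- random_rotation()
    sR <- stress_neo_hookean(R %*% F0, mats$mu, mats$kappa)
    expect_equal(sR$ps, s0$ps, tolerance = 1e-10)
    expect_equal(sR$dev_sigma, R %*% s0$dev_sigma %*% t(R),
                 tolerance = 1e-9)
  }
})

test_that("assembled tangent matches finite differences", {
  set.seed(7)
  mesh <- aneufsi:::make_octant_shell(2, 0.3, 1L, 2L)
  setup <- aneufsi:::solid_setup(mesh, solid_params(),
                                 constraints = list(fixed_nodes = integer(0)))
  n <- nrow(mesh$vertices)
  u <- matrix(rnorm(3 * n, 0, 2e-5), n, 3)
  ps <- rnorm(n, 0, 200)
  tr <- fem_assemble_solid(setup$V0, setup$T, setup$geo$vol,
                           setup$geo$grad, u, ps, setup$mu_e,
                           setup$kappa_e, setup$tau_e)
  A <- aneufsi:::triplet_sparse(tr, 4L * n)
  # central differences with dof-appropriate steps
  for (d in sample(4L * n, 8L)) {
    eps <- if (d <= 3 * n) 1e-9 else 1e-2
    pert <- function(sgn) {
      uu <- u; pp <- ps
      if (d <= 3 * n) uu[((d - 1) %% n) + 1, ((d - 1) %/% n) + 1] <-
          uu[((d - 1) %% n) + 1, ((d - 1) %/% n) + 1] + sgn * eps
      else pp[d - 3 * n] <- pp[d - 3 * n] + sgn * eps
      fem_assemble_solid(setup$V0, setup$T, setup$geo$vol, setup$geo$grad,
                         uu, pp, setup$mu_e, setup$kappa_e, setup$tau_e)$res
    }
    fd <- (pert(1) - pert(-1)) / (2 * eps)
    an <- as.numeric(A[, d])
    expect_lt(max(abs(fd - an)) / max(max(abs(an)), 1e-12), 1e-6)
  }
})

test_that("uniform-traction bar passes the small-strain patch test", {
  mesh <- make_box_mesh(1, 4, 1, 2L, 6L, 2L)
  E <- 0.75; nu <- 0.45
  setup <- aneufsi:::solid_setup(mesh, solid_params(E, E, nu),
                                 constraints = list(fixed_nodes = integer(0)))
  V <- mesh$vertices
  n <- nrow(V)
  tol <- 1e-9
  # symmetry constraints on three coordinate planes
  setup$fixed_dofs <- c(which(abs(V[, 1]) < tol),
                        n + which(abs(V[, 2]) < tol),
                        2L * n + which(abs(V[, 3]) < tol))
  sig <- E * 1e6 * 1e-4   # target uniaxial stress for strain 1e-4, Pa
  faces <- mesh_faces_by_tag(mesh, "ymax")
  fg <- aneufsi:::face_geometry(setup$V0, faces)
  f_ext <- surface_load_vector(n, faces,
                               matrix(rep(c(0, sig, 0), each = nrow(faces)),
                                      ncol = 3), fg$area)
  st <- solve_static_solid(setup, f_ext, n_ramp = 1L)
  cs <- solid_cauchy_stress(setup, st)
  syy <- cs$sigma[, 2, 2]
  expect_lt(max(abs(syy - sig)) / sig, 0.01)          # homogeneous stress
  expect_lt(max(abs(cs$sigma[, 1, 1])) / sig, 0.01)   # lateral stress free
  # axial strain matches linear elasticity
  eyy <- max(st$u[, 2]) * 1e3 / 4
  expect_lt(abs(eyy - 1e-4) / 1e-4, 0.01)
})

test_that("thin-shell inflation recovers the Laplace hoop stress", {
  r <- inflation_result()
  expect_lt(rel_err(r$hoop, r$hoop_expected), 0.05)
})

test_that("higher bulk modulus drives the inflation toward isochoric", {
  jdev <- function(nu) {
    r <- aneufsi:::run_inflation_check(nu = nu, subdiv = 4L)
    setup <- aneufsi:::solid_setup(r$mesh, solid_params(0.75, 0.75, nu),
                                   constraints = list(fixed_nodes = integer(0)))
    cs <- solid_cauchy_stress(setup, r$state)
    sum(abs(cs$J - 1) * setup$geo$vol) / sum(setup$geo$vol)
  }
  expect_lt(jdev(0.49), jdev(0.3))
})

test_that("external work balances stored energy on a quasi-static path", {
  mesh <- make_box_mesh(1, 2, 1, 2L, 4L, 2L)
  setup <- aneufsi:::solid_setup(mesh, solid_params(0.75, 0.75),
                                 constraints = list(fixed_nodes = integer(0)))
  V <- mesh$vertices; n <- nrow(V); tol <- 1e-9
  setup$fixed_dofs <- c(which(abs(V[, 1]) < tol),
                        n + which(abs(V[, 2]) < tol),
                        2L * n + which(abs(V[, 3]) < tol))
  sig <- 2e3   # Pa: small strain so work ~ (1/2) f.u
  faces <- mesh_faces_by_tag(mesh, "ymax")
  fg <- aneufsi:::face_geometry(setup$V0, faces)
  f_ext <- surface_load_vector(n, faces,
                               matrix(rep(c(0, sig, 0), each = nrow(faces)),
                                      ncol = 3), fg$area)
  st <- solve_static_solid(setup, f_ext, n_ramp = 4L)
  work <- 0.5 * sum(f_ext * as.numeric(st$u))
  stored <- solid_stored_energy(setup, st)
  expect_lt(abs(work - stored) / work, 0.02)
})

test_that("zero load and zero history keep the solid at rest", {
  mesh <- coarse_tube_shell()
  setup <- aneufsi:::solid_setup(mesh, solid_params())
  st <- aneufsi:::new_solid_state(setup$n)
  for (k in 1:2)
    st <- advance_solid(setup, st, NULL, dt = 1e-3)
  expect_lt(max(abs(st$u)), 1e-12)
})
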