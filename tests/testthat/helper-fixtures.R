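# Shared fixtures, memoized so expensive meshes are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, builder) {
  v <- .fixture_env[[key]]
  if (is.null(v)) {
    v <- builder()
    .fixture_env[[key]] <- v
  }
  v
}

coarse_tube <- function() memo_fixture("tube", function()
  make_tube_fixture(2, 20, resolution = 1))

coarse_tube_shell <- function() memo_fixture("tube_shell", function()
  make_tube_shell(coarse_tube(), 0.25, 2L))

case_r_model <- function() memo_fixture("model", function() build_case_r())

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

vec_norms <- function(m) sqrt(rowSums(m^2))

# random rotation matrix from a fixed-seed QR factorization
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# heavy fixture runs shared between the module tests and the acceptance
# suite (each is computed once per test session)
poiseuille_result <- function() memo_fixture("poiseuille", function()
  aneufsi:::run_poiseuille_check())

womersley_result <- function() memo_fixture("womersley", function()
  aneufsi:::run_womersley_check())

inflation_result <- function() memo_fixture("inflation", function()
  aneufsi:::run_inflation_check())

pressure_wave_result <- function() memo_fixture("pressure_wave", function()
  aneufsi:::run_pressure_wave_check())

# rigid-limit comparison of the coupled solver against pure CFD on a short
# elastic tube with the stiffness scaled by 1e6
rigid_limit_result <- function() memo_fixture("rigid_limit", function() {
  radius <- 2; len <- 10
  fl_mesh <- make_tube_fixture(radius, len, 0.9)
  sl_mesh <- make_tube_shell(fl_mesh, 0.25, 1L)
  wf <- build_waveform(shape_spec = function(tt) rep(1, length(tt)),
                       target_mean_flow = 3, inlet_area = pi * radius^2,
                       ramp = 5e-3)
  fls <- fluid_setup(fl_mesh, fluid_params(), waveform = wf,
                     outlet = outlet_model(P0 = 0, Rd = 0.2))
  tolp <- 1e-6
  fix <- which(abs(sl_mesh$vertices[, 2]) < tolp |
                 abs(sl_mesh$vertices[, 2] - len) < tolp)
  sls <- aneufsi:::solid_setup(
    sl_mesh, solid_params(E_bulge = 0.75e6, E_artery = 0.75e6),
    constraints = list(fixed_nodes = fix))
  imap <- aneufsi:::match_interface(fl_mesh, sl_mesh, fls$interface_nodes,
                                    sls$interface_nodes)
  fls_r <- fluid_setup(fl_mesh, fluid_params(), waveform = wf,
                       outlet = outlet_model(P0 = 0, Rd = 0.2))
  stc <- list(flow = aneufsi:::new_flow_state(fls$n), flow2 = NULL,
              solid = aneufsi:::new_solid_state(sls$n), solid2 = NULL,
              d1 = NULL, d2 = NULL)
  str <- list(flow = aneufsi:::new_flow_state(fls_r$n), flow2 = NULL)
  dt <- 1e-3
  res <- NULL
  for (k in 1:5) {
    res <- coupled_step(fls, sls, imap, stc, k * dt, dt, coupling_config())
    stc$flow2 <- stc$flow; stc$flow <- res$flow
    stc$solid2 <- stc$solid; stc$solid <- res$solid
    stc$d2 <- stc$d1; stc$d1 <- res$motion$d_mesh
    rigid <- advance_fluid(fls_r, str$flow, str$flow2, k * dt, dt)
    str$flow2 <- str$flow; str$flow <- rigid
  }
  list(max_u_mm = max(vec_norms(stc$solid$u)) * 1e3,
       v_l2_rel = sqrt(sum((stc$flow$v - str$flow$v)^2)) /
         sqrt(sum(str$flow$v^2)),
       last_r = tail(res$log$r_norm, 1), log = res$log)
})

# full desk-scale rigid/compliant case pair on a shared mesh
case_pair_result <- function() memo_fixture("case_pair", function() {
  cfg_c <- case_config(mode = "compliant", store_every = 2L)
  ms <- aneufsi:::build_case_meshes(cfg_c)
  bc <- run_case(cfg_c, meshes = ms)
  br <- run_case(case_config(mode = "rigid", store_every = 2L), meshes = ms)
  list(rigid = br, compliant = bc, cmp = compare_modes(br, bc))
})
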