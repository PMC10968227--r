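test_that("tube fixture matches analytic section area and volume", {
  m <- make_tube_fixture(2, 20, resolution = 2)
  ig <- aneufsi:::face_geometry(m$vertices, mesh_faces_by_tag(m, "inlet"))
  expect_lt(rel_err(sum(ig$area), pi * 4), 0.01)
  expect_lt(rel_err(sum(mesh_cell_volumes(m)), pi * 4 * 20), 0.01)
  expect_error(make_tube_fixture(2, 20, resolution = 0), "positive")
})

test_that("meshes are watertight with matched boundary tagging", {
  m <- coarse_tube()
  expect_true(mesh_check_watertight(m))
  s <- coarse_tube_shell()
  expect_true(mesh_check_watertight(s))
  expect_setequal(unique(s$boundary_tags), c("interface", "exterior", "fixed"))
})

test_that("fluid and solid interface triangulations are vertex-identical", {
  m <- coarse_tube()
  s <- coarse_tube_shell()
  fi <- sort(unique(as.integer(mesh_faces_by_tag(m, "interface"))))
  si <- sort(unique(as.integer(mesh_faces_by_tag(s, "interface"))))
  expect_equal(length(fi), length(si))
  kf <- apply(m$vertices[fi, ], 1, paste, collapse = ",")
  ks <- apply(s$vertices[si, ], 1, paste, collapse = ",")
  expect_setequal(kf, ks)
})

test_that("shell thickness along normals matches the wall thickness", {
  s <- coarse_tube_shell()
  # extruded tube shell: outer radius - inner radius = thickness
  r <- vec_norms(s$vertices[, c(1, 3)])
  expect_lt(abs(max(r) - min(r) - 0.25), 0.25 * 0.02)
  # case-R wall: distance from base shell vertex to its outermost mate
  model <- case_r_model()
  fl <- mesh_fluid(model, mesh_params(core_size = 0.9,
                                      bl_first_layer = 0.3,
                                      bl_total = 0.45), scale = 1)
  sl <- mesh_solid(fl, model)
  np <- sl$meta$np; nl <- sl$meta$nl
  d <- vec_norms(sl$vertices[nl * np + seq_len(np), ] -
                   sl$vertices[seq_len(np), ])
  expect_lt(max(abs(d - 0.25)), 0.25 * 0.02)
})

test_that("cell count grows monotonically under refinement", {
  n1 <- nrow(make_tube_fixture(2, 10, resolution = 1)$cells)
  n2 <- nrow(make_tube_fixture(2, 10, resolution = 1.5)$cells)
  expect_gt(n2, n1)
  model <- case_r_model()
  c1 <- nrow(mesh_fluid(model, mesh_params(core_size = 1.0))$cells)
  c2 <- nrow(mesh_fluid(model, mesh_params(core_size = 0.5))$cells)
  expect_gt(c2, c1)
})

test_that("boundary-layer grading hits the first-layer thickness", {
  mp <- mesh_params()
  rl <- aneufsi:::radial_levels(2, mp$core_size, mp$bl_first_layer,
                                mp$bl_growth, mp$bl_total)
  spacing <- diff(rl)
  # wall-adjacent spacing equals the prescribed first layer
  expect_lt(abs(tail(spacing, 1) - 0.02), 0.02 * 0.2)
  # geometric growth inward through the layer, cumulative >= total
  bl <- rev(spacing)[1:8]
  expect_lt(max(abs(bl[-1] / bl[-8] - 1.2)), 0.01)
  expect_gte(sum(bl), 0.3)
})

test_that("case-R geometry is symmetric and guards invalid inputs", {
  model <- case_r_model()
  # mirror symmetry about the vessel mid-plane (theta -> pi - theta)
  th <- c(0.3, 0.9, 1.2); ph <- c(0.5, 2, 4)
  expect_equal(aneufsi:::case_r_rho(model, th, ph),
               aneufsi:::case_r_rho(model, pi - th, ph), tolerance = 1e-10)
  # z-mirror symmetry (phi -> -phi)
  expect_equal(aneufsi:::case_r_rho(model, th, ph),
               aneufsi:::case_r_rho(model, th, -ph), tolerance = 1e-10)
  expect_error(build_case_r(case_geometry_params(bulge_radius = 1e-13)),
               "bulge|positive")
  expect_error(build_case_r(case_geometry_params(bulge_radius = 1.5)),
               "intersect")
  expect_error(case_geometry_params(bulge_cut_height = 11), "below")
  expect_error(case_geometry_params(inlet_diameter = 13), "torus")
})

test_that("region tagging partitions wall cells at the cut plane", {
  s <- tag_regions(coarse_tube_shell(), 8)
  cen_y <- (s$vertices[s$cells[, 1], 2] + s$vertices[s$cells[, 2], 2] +
              s$vertices[s$cells[, 3], 2] + s$vertices[s$cells[, 4], 2]) / 4
  expect_setequal(unique(s$region), c("bulge-wall", "artery-wall"))
  expect_true(all((s$region == "bulge-wall") == (cen_y > 8)))
  # every cell with all vertices above the plane is bulge-wall
  ally <- matrix(s$vertices[s$cells, 2], ncol = 4)
  expect_true(all(s$region[rowSums(ally > 8) == 4L] == "bulge-wall"))
  # cut above the domain -> no bulge cells
  s2 <- tag_regions(coarse_tube_shell(), 100)
  expect_false(any(s2$region == "bulge-wall"))
})

test_that("solid layering scales element counts with layer number", {
  m <- coarse_tube()
  s6 <- make_tube_shell(m, 0.25, 6L)
  s1 <- make_tube_shell(m, 0.25, 1L)
  expect_lt(abs(nrow(s1$cells) / nrow(s6$cells) - 1 / 6), 1 / 6 * 0.25)
})
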