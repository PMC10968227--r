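test_that("MSH write/read round trip preserves the tagged mesh", {
  m <- tag_regions(coarse_tube_shell(), 8)
  path <- tempfile(fileext = ".msh")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_equal(m2$vertices, m$vertices)
  # tags survive; faces/cells may be reordered by tag blocks
  key <- function(f) sort(apply(f, 1, function(r) paste(sort(r), collapse = "_")))
  expect_equal(key(m2$boundary_faces), key(m$boundary_faces))
  expect_equal(sort(table(m2$boundary_tags)), sort(table(m$boundary_tags)))
  expect_equal(sort(table(m2$region)), sort(table(m$region)))
  # cells as sets
  expect_equal(sort(apply(m2$cells, 1, function(r) paste(sort(r), collapse = "_"))),
               sort(apply(m$cells, 1, function(r) paste(sort(r), collapse = "_"))))
})

test_that("mesh files without boundary tags are rejected", {
  m <- coarse_tube()
  path <- tempfile(fileext = ".msh")
  write_mesh(m, path)
  txt <- readLines(path)
  # strip the physical-names section
  i0 <- match("$PhysicalNames", txt); i1 <- match("$EndPhysicalNames", txt)
  writeLines(txt[-(i0:i1)], path)
  expect_error(read_mesh(path), "physical|tags")
  expect_error(read_mesh(tempfile()), "not found")
})

test_that("VTU export writes well-formed XML with point data", {
  m <- coarse_tube()
  path <- tempfile(fileext = ".vtu")
  write_vtu(m, path, point_data = list(speed = rowSums(m$vertices^2),
                                       vel = m$vertices))
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "VTKFile")
  pieces <- xml2::xml_find_all(doc, ".//Piece")
  expect_equal(as.integer(xml2::xml_attr(pieces, "NumberOfPoints")),
               nrow(m$vertices))
  expect_equal(length(xml2::xml_find_all(doc, ".//PointData/DataArray")), 2L)
})
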