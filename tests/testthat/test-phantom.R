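test_that("phantom stack has the expected regions, volume and node sets", {
  mesh <- fix_small_mesh()
  expect_setequal(unique(mesh$region), c("vertebra_1", "disc_1", "vertebra_2"))
  expect_true(all(tet_volumes(mesh$nodes, mesh$tets) > 0))

  # tet volumes must reproduce the prism volume of the generating solid
  expect_equal(sum(tet_volumes(mesh$nodes, mesh$tets)),
               phantom_prism_volume(mesh), tolerance = 1e-9)

  # regions partition the volume
  vol <- tet_volumes(mesh$nodes, mesh$tets)
  expect_equal(sum(tapply(vol, mesh$region, sum)), sum(vol), tolerance = 1e-12)

  # interface node sets shared between neighbouring regions
  expect_identical(mesh$node_sets$vertebra_1_upper, mesh$node_sets$disc_1_lower)
  expect_identical(mesh$node_sets$disc_1_upper, mesh$node_sets$vertebra_2_lower)
  expect_identical(mesh$node_sets$bottom, mesh$node_sets$vertebra_1_lower)
})

test_that("default phantom is an L1-L5-like stack of 5 vertebrae and 4 discs", {
  mesh <- fix_study_mesh()
  expect_length(grep("^vertebra", unique(mesh$region)), 5L)
  expect_length(grep("^disc", unique(mesh$region)), 4L)
  expect_equal(sum(tet_volumes(mesh$nodes, mesh$tets)),
               phantom_prism_volume(mesh), tolerance = 1e-9)
})

test_that("cylinder phantoms also close their volume against the prism oracle", {
  mesh <- build_phantom(phantom_spec(n_vertebrae = 1, cross_section = "cylinder",
                                     radius = 15, vertebra_height = 12,
                                     mesh_resolution = 4))
  expect_equal(sum(tet_volumes(mesh$nodes, mesh$tets)),
               phantom_prism_volume(mesh), tolerance = 1e-9)
})

test_that("single-vertebra phantom degenerates to one region without discs", {
  mesh <- build_phantom(phantom_spec(n_vertebrae = 1, mesh_resolution = 10))
  expect_identical(unique(mesh$region), "vertebra_1")
  expect_false(any(grepl("^disc", names(mesh$node_sets))))
  expect_true(all(c("top", "bottom", "vertebra_1_lower", "vertebra_1_upper")
                  %in% names(mesh$node_sets)))
})

test_that("phantom generation is reproducible and validates its spec", {
  a <- build_phantom(phantom_spec(mesh_resolution = 10))
  b <- build_phantom(phantom_spec(mesh_resolution = 10))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$tets, b$tets)
  expect_error(phantom_spec(n_vertebrae = 0), "n_vertebrae")
  expect_error(phantom_spec(vertebra_height = -1), "positive")
  expect_error(phantom_spec(mesh_resolution = 0), "positive")
})

test_that("generated phantom surfaces are watertight and outward-oriented", {
  mesh <- fix_small_mesh()
  surf <- extract_surface(mesh)
  expect_true(surf$watertight)
  # outward orientation: divergence theorem gives the enclosed volume
  a <- surf$vertices[surf$triangles[, 1], ]
  b <- surf$vertices[surf$triangles[, 2], ]
  c <- surf$vertices[surf$triangles[, 3], ]
  vol <- sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
               a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
               a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  expect_equal(vol, sum(tet_volumes(mesh$nodes, mesh$tets)), tolerance = 1e-9)
})

test_that("endplate annotation picks exactly the flat faces of a cube", {
  surf <- fix_cube_surface()
  ann <- annotate_endplates(surf, max_angle_deg = 10, distance_band = NULL)
  # upper set: the two z = 1 triangles (indices 3, 4); lower: z = 0 (1, 2)
  expect_setequal(ann$upper, c(3L, 4L))
  expect_setequal(ann$lower, c(1L, 2L))
})

test_that("endplate annotation equals an exhaustive per-triangle filter", {
  mesh <- build_phantom(phantom_spec(n_vertebrae = 1, mesh_resolution = 6))
  surf <- extract_surface(mesh)
  max_angle <- 25
  band <- c(-1, 29)
  ann <- annotate_endplates(surf, max_angle_deg = max_angle,
                            distance_band = band)
  # independent brute-force filter
  cen <- (surf$vertices[surf$triangles[, 1], ] +
            surf$vertices[surf$triangles[, 2], ] +
            surf$vertices[surf$triangles[, 3], ]) / 3
  up <- lo <- integer(0)
  for (t in seq_len(nrow(surf$triangles))) {
    ang_up <- acos(max(-1, min(1, surf$normals[t, 3]))) * 180 / pi
    ang_lo <- acos(max(-1, min(1, -surf$normals[t, 3]))) * 180 / pi
    in_band <- cen[t, 3] >= band[1] && cen[t, 3] <= band[2]
    if (ang_up <= max_angle && in_band) up <- c(up, t)
    if (ang_lo <= max_angle && in_band) lo <- c(lo, t)
  }
  expect_setequal(ann$upper, up)
  expect_setequal(ann$lower, setdiff(lo, up))

  # idempotence / order independence: a pure per-triangle predicate
  perm <- rev(seq_len(nrow(surf$triangles)))
  surf2 <- surface_mesh(surf$vertices, surf$triangles[perm, ])
  ann2 <- annotate_endplates(surf2, max_angle_deg = max_angle,
                             distance_band = band)
  expect_setequal(perm[ann2$upper], ann$upper)
})

test_that("near-zero selection angle yields empty endplate sets with a warning", {
  mesh <- build_phantom(phantom_spec(n_vertebrae = 1, mesh_resolution = 8))
  surf <- extract_surface(mesh)
  # tilt the axis so that no normal is exactly parallel to it
  axis <- c(1e-3, 2e-3, 1)
  expect_warning(expect_warning(
    ann <- annotate_endplates(surf, max_angle_deg = 1e-8, axis = axis),
    "empty"), "empty")
  expect_length(ann$upper, 0L)
  expect_length(ann$lower, 0L)
  expect_error(annotate_endplates(surf, max_angle_deg = 0), "between 0 and 90")
  expect_error(annotate_endplates(surf, max_angle_deg = 95), "between 0 and 90")
})

test_that("a vertebra-scale surface reaches the 6000-7000 triangle band", {
  mesh <- build_phantom(phantom_spec(n_vertebrae = 1, mesh_resolution = 1.55))
  surf <- extract_surface(mesh)
  expect_gte(nrow(surf$triangles), 6000L)
  expect_lte(nrow(surf$triangles), 7000L)
})

test_that("STL files round-trip through both encodings", {
  surf <- extract_surface(fix_small_mesh())
  for (binary in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(surf, path, binary = binary)
    back <- read_stl(path)
    expect_identical(nrow(back$triangles), nrow(surf$triangles))
    # float32 STL precision
    a <- surf$vertices[surf$triangles[, 1], ]
    b <- back$vertices[back$triangles[, 1], ]
    expect_equal(a, b, tolerance = 1e-6, ignore_attr = TRUE)
    expect_true(back$watertight)
  }
})

test_that("single-triangle ASCII STL parses to 3 vertices and 1 triangle", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c(
    "solid one",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 0",
    "      vertex 0 1 0",
    "    endloop",
    "  endfacet",
    "endsolid one"), path)
  m <- read_stl(path)
  expect_identical(nrow(m$vertices), 3L)
  expect_identical(nrow(m$triangles), 1L)
  expect_equal(m$normals[1, ], c(0, 0, 1))
})

test_that("malformed STL input reports the offending location", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c(
    "solid bad",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 zero",
    "    endloop",
    "  endfacet",
    "endsolid bad"), path)
  expect_error(read_stl(path), "line 5")
  # truncated binary: header promises more triangles than the file holds
  bpath <- withr::local_tempfile(fileext = ".stl")
  con <- file(bpath, "wb")
  writeBin(raw(80), con)
  writeBin(1000L, con, size = 4L, endian = "little")
  writeBin(raw(10), con)
  close(con)
  expect_error(read_stl(bpath), "byte")
})

test_that("VTK unstructured-grid interchange preserves the labeled mesh", {
  mesh <- fix_small_mesh()
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(mesh, path)
  back <- read_vtk(path)
  expect_equal(back$nodes, mesh$nodes, ignore_attr = TRUE)
  expect_identical(back$tets, mesh$tets)
  expect_identical(back$region, mesh$region)
  expect_setequal(back$node_sets$bottom, mesh$node_sets$bottom)
  expect_setequal(back$node_sets$top, mesh$node_sets$top)
})
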