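patch_box <- function(E = 1e9, height = 20, res = 5) {
  mesh <- build_phantom(phantom_spec(n_vertebrae = 1, vertebra_height = height,
                                     cross_section = "box",
                                     half_width = c(10, 10),
                                     mesh_resolution = res))
  mat <- material_properties(E_bone = E, nu_bone = 0,
                             E_disc = 1e6, nu_disc = 0)
  list(mesh = mesh, mat = mat)
}

test_that("constant-strain patch test is exact to machine precision", {
  p <- patch_box()
  sol <- assemble_and_solve(p$mesh, p$mat, load_case(1))
  eps_expect <- -1e-3 / 20e-3
  expect_lt(max(abs(sol$strain[, 3] - eps_expect)), 1e-12 * abs(eps_expect))
  expect_lt(max(abs(sol$strain[, -3])), 1e-12)
  # homogeneous state: extracted sigma_z equals E * eps_z exactly
  feat <- extract_features(sol, p$mesh)
  expect_equal(feat[["sigma_z"]], 1e9 * eps_expect, tolerance = 1e-12)
  expect_equal(feat[["eps_z"]], eps_expect, tolerance = 1e-12)
})

test_that("doubling the prescribed displacement doubles force and stress", {
  p <- patch_box()
  s1 <- assemble_and_solve(p$mesh, p$mat, load_case(0.7))
  s2 <- assemble_and_solve(p$mesh, p$mat, load_case(1.4))
  expect_equal(s2$F_ext, 2 * s1$F_ext, tolerance = 1e-10)
  expect_equal(s2$stress, 2 * s1$stress, tolerance = 1e-10)
  expect_equal(s2$u, 2 * s1$u, tolerance = 1e-10)
})

test_that("global force and energy balances hold", {
  mesh <- fix_small_mesh()
  mat <- material_properties(15e9, 0.3, 2e6, 0.45)
  sol <- assemble_and_solve(mesh, mat, load_case(1))
  # reaction on the constrained set balances the loaded set
  expect_lt(abs(sol$F_ext + sol$F_top), 1e-8 * abs(sol$F_ext))
  # external work 1/2 F u equals stored strain energy
  w_ext <- 0.5 * abs(sol$F_top) * 1e-3
  expect_lt(abs(w_ext - sol$energy), 1e-8 * sol$energy)
})

test_that("layered bar matches the series-spring closed form", {
  # uniaxial, laterally unconstrained variant: nu = 0 in both layers
  mesh <- build_phantom(phantom_spec(n_vertebrae = 2, vertebra_height = 20,
                                     disc_height = 10, cross_section = "box",
                                     half_width = c(5, 5),
                                     mesh_resolution = 2.5))
  E_b <- 15e9; E_d <- 2e6
  mat <- material_properties(E_b, 0, E_d, 0)
  sol <- assemble_and_solve(mesh, mat, load_case(
    0.5, constraint_mode = "rollers_z"))
  A <- 0.01 * 0.01
  k_series <- 1 / (2 * 0.020 / (E_b * A) + 0.010 / (E_d * A))
  expect_equal(sol$F_ext, k_series * 0.5e-3, tolerance = 0.01)
})

test_that("stiffness decreases monotonically under mesh refinement", {
  mat <- material_properties(15e9, 0.3, 2e6, 0.45)
  F <- vapply(c(10, 5, 2.5), function(res) {
    mesh <- build_phantom(phantom_spec(n_vertebrae = 2, vertebra_height = 20,
                                       disc_height = 10,
                                       cross_section = "box",
                                       half_width = c(10, 10),
                                       mesh_resolution = res))
    assemble_and_solve(mesh, mat, load_case(0.5))$F_ext
  }, numeric(1))
  # displacement-based elements are too stiff; refining relaxes them
  expect_true(all(diff(F) < 0))
})

test_that("response features are invariant under mesh renumbering", {
  mesh <- fix_small_mesh()
  mat <- material_properties(12e9, 0.25, 3e6, 0.46)
  load <- load_case(1)
  f1 <- extract_features(assemble_and_solve(mesh, mat, load), mesh)
  pm <- spinepinn:::permute_mesh(mesh, seed = 42)
  f2 <- extract_features(assemble_and_solve(pm, mat, load), pm)
  expect_equal(f1, f2, tolerance = 1e-9)
  f3 <- extract_features(assemble_and_solve(pm, mat, load), pm,
                         aggregation = "volume_mean")
  f4 <- extract_features(assemble_and_solve(mesh, mat, load), mesh,
                         aggregation = "volume_mean")
  expect_equal(f3, f4, tolerance = 1e-9)
})

test_that("axisymmetric phantom under axial compression has no mean shear", {
  mesh <- fix_study_mesh()
  mat <- material_properties(15e9, 0.3, 2e6, 0.46)
  feat <- extract_features(assemble_and_solve(mesh, mat, load_case(1.4)), mesh)
  dominant <- abs(feat[["sigma_z"]])
  expect_lt(max(abs(feat[c("sigma_xy", "sigma_yz", "sigma_xz")])),
            1e-8 * dominant)
  expect_lt(max(abs(feat[c("eps_xy", "eps_yz", "eps_xz")])),
            1e-8 * abs(feat[["eps_z"]]))
})

test_that("quasi-static step table scales linearly and matches re-solving", {
  mesh <- fix_small_mesh()
  mat <- material_properties(15e9, 0.3, 2e6, 0.45)
  sol <- assemble_and_solve(mesh, mat, load_case(1, n_steps = 10))
  expect_identical(nrow(sol$steps), 10L)
  expect_equal(sol$steps$F_ext_N, sol$F_ext * (1:10) / 10, tolerance = 1e-12)
  resolved <- assemble_and_solve(mesh, mat, load_case(1, n_steps = 5),
                                 rescale_steps = FALSE)
  expect_equal(resolved$steps$F_ext_N, resolved$F_ext * (1:5) / 5,
               tolerance = 1e-9)
})

test_that("ill-posed load cases raise explicit errors", {
  mesh <- fix_small_mesh()
  mat <- material_properties(15e9, 0.3, 2e6, 0.45)
  bad <- load_case(1, constrained = "nope")
  expect_error(assemble_and_solve(mesh, mat, bad), "unknown node set")
  overlap <- load_case(1, constrained = "top", loaded = "top")
  expect_error(assemble_and_solve(mesh, mat, overlap), "disjoint")
  # inverted element
  broken <- mesh
  broken$tets[1, 2:3] <- broken$tets[1, 3:2]
  expect_error(assemble_and_solve(broken, mat, load_case(1)),
               "non-positive")
  expect_error(load_case(-1), "positive")
})
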