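test_that("material sampling stays in bounds and is reproducible", {
  r <- sampling_ranges()
  mats <- sample_materials(r, 404, seed = 3)
  expect_length(mats, 404)
  E_b <- vapply(mats, `[[`, numeric(1), "E_bone") / 1e9
  E_d <- vapply(mats, `[[`, numeric(1), "E_disc") / 1e6
  nu_b <- vapply(mats, `[[`, numeric(1), "nu_bone")
  nu_d <- vapply(mats, `[[`, numeric(1), "nu_disc")
  expect_true(all(E_b >= 10 & E_b <= 25))
  expect_true(all(E_d >= 1 & E_d <= 4.1))
  expect_true(all(nu_b >= 0.1 & nu_b <= 0.4))
  expect_true(all(nu_d >= 0.45 & nu_d <= 0.48))
  expect_identical(sample_materials(r, 10, seed = 3),
                   sample_materials(r, 10, seed = 3))
})

test_that("derived moduli and densities follow their generating relations", {
  r <- sampling_ranges()
  mats <- sample_materials(r, 50, seed = 5)
  for (m in mats) {
    iso <- isotropic_relations(m$E_bone, m$nu_bone)
    expect_equal(m$k_bone, iso$k, tolerance = 1e-10)
    expect_equal(m$mu_bone, iso$mu, tolerance = 1e-10)
  }
  # density is a monotone (affine) image of E through the latent HU
  E_b <- vapply(mats, `[[`, numeric(1), "E_bone")
  rho_b <- vapply(mats, `[[`, numeric(1), "rho_bone")
  expect_equal(cor(E_b, rho_b), 1, tolerance = 1e-9)
  expect_true(all(rho_b >= r$c_bone + r$d_bone * r$hu_bone[1]))
  expect_true(all(rho_b <= r$c_bone + r$d_bone * r$hu_bone[2]))
})

test_that("degenerate sampling ranges collapse to their single value", {
  r <- sampling_ranges(E_bone_GPa = c(12, 12), nu_bone = c(0.3, 0.3))
  mats <- sample_materials(r, 5, seed = 1)
  expect_true(all(vapply(mats, `[[`, numeric(1), "E_bone") == 12e9))
  expect_true(all(vapply(mats, `[[`, numeric(1), "nu_bone") == 0.3))
})

test_that("uniform sampling is not rejected by a coarse KS check", {
  r <- sampling_ranges()
  mats <- sample_materials(r, 1e4, seed = 11)
  E_b <- vapply(mats, `[[`, numeric(1), "E_bone") / 1e9
  expect_gt(suppressWarnings(
    stats::ks.test(E_b, "punif", 10, 25)$p.value), 0.001)
  expect_gte(min(E_b), 10)
  expect_lte(max(E_b), 25)
})

test_that("invalid ranges are refused", {
  expect_error(sampling_ranges(E_bone_GPa = c(25, 10)), "increasing")
  expect_error(sampling_ranges(nu_disc = c(0.45, 0.5)), "below 0.5")
  expect_error(load_sweep(c(0.4, 0.2)), "increasing")
  expect_error(load_sweep(c(-0.2, 0.4)), "positive")
})

test_that("dataset has one row per material-magnitude pair", {
  ds <- fix_dataset()
  expect_identical(dim(ds$X), c(406L, 16L))
  expect_identical(dim(ds$Y), c(406L, 10L))
  expect_identical(colnames(ds$X), feature_names())
  expect_identical(colnames(ds$Y), target_names())
  expect_false(anyNA(ds$X))
  # target rows are internally consistent
  iso <- isotropic_relations(ds$Y[, "E_bone_GPa"], ds$Y[, "nu_bone"])
  expect_equal(ds$Y[, "k_bone_GPa"], iso$k, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(ds$Y[, "mu_bone_GPa"], iso$mu, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("single material and magnitude give one row carrying the draw", {
  mesh <- fix_small_mesh()
  ds <- build_dataset(mesh, sweep = load_sweep(1.4), n_materials = 1, seed = 9)
  expect_identical(nrow(ds$X), 1L)
  mat <- sample_materials(sampling_ranges(), 1, seed = 9)[[1]]
  expect_equal(ds$Y[1, ], spinepinn:::properties_to_targets(mat),
               tolerance = 1e-12)
})

test_that("applied force grows strictly with load magnitude per material", {
  ds <- fix_dataset()
  for (g in unique(ds$group)[1:5]) {
    F <- ds$X[ds$group == g, "F_ext"]
    expect_true(all(diff(F) > 0))
  }
})

test_that("dataset CSV export is deterministic and round-trips", {
  mesh <- fix_small_mesh()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(build_dataset(mesh, sweep = load_sweep(c(0.5, 1)),
                                  n_materials = 3, seed = 4), p1)
  write_dataset_csv(build_dataset(mesh, sweep = load_sweep(c(0.5, 1)),
                                  n_materials = 3, seed = 4), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_dataset_csv(p1)
  expect_identical(dim(back$X), c(6L, 16L))
})

test_that("row-level split follows largest-remainder rounding", {
  ds <- fix_toy_dataset(n = 678)
  ds <- split_and_normalize(ds, c(0.7, 0.15, 0.15), seed = 2, by = "row")
  expect_identical(lengths(ds$splits), c(train = 474L, val = 102L,
                                         test = 102L))
  idx <- sort(unname(unlist(ds$splits)))
  expect_identical(idx, 1:678)
})

test_that("material-level split keeps all rows of a material together", {
  ds <- fix_dataset()
  for (s in names(ds$splits)) {
    gs <- unique(ds$group[ds$splits[[s]]])
    others <- unlist(lapply(setdiff(names(ds$splits), s),
                            function(o) ds$group[ds$splits[[o]]]))
    expect_length(intersect(gs, unique(others)), 0L)
  }
  expect_identical(sort(unname(unlist(ds$splits))), seq_len(nrow(ds$X)))
})

test_that("normalisation statistics never see validation or test rows", {
  ds <- fix_toy_dataset(n = 60)
  s1 <- split_and_normalize(ds, seed = 3, by = "row")
  tampered <- ds
  notrain <- c(s1$splits$val, s1$splits$test)
  tampered$X[notrain, ] <- tampered$X[notrain, ] * 100 + 7
  tampered$Y[notrain, ] <- tampered$Y[notrain, ] * 100 + 7
  s2 <- split_and_normalize(tampered, seed = 3, by = "row")
  expect_identical(s1$splits, s2$splits)
  expect_equal(s1$stats$x_mean, s2$stats$x_mean, tolerance = 1e-12)
  expect_equal(s1$stats$y_sd, s2$stats$y_sd, tolerance = 1e-12)
})

test_that("normalise and denormalise are inverse on the training split", {
  ds <- fix_dataset()
  tr <- ds$splits$train
  Z <- spinepinn:::normalize_cols(ds$X[tr, ], ds$stats$x_mean, ds$stats$x_sd)
  back <- spinepinn:::denormalize_cols(Z, ds$stats$x_mean, ds$stats$x_sd)
  expect_equal(back, ds$X[tr, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_no_error(split_and_normalize(ds, c(0.9, 0.05, 0.05), seed = 1,
                                      by = "row"))
  expect_error(split_and_normalize(fix_toy_dataset(4), c(0.999, 5e-4, 5e-4),
                                   by = "row"),
               "fewer than 1")
})
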