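# Shared fixtures, built lazily once per test session. The heavier
# objects (the study-scale phantom, datasets and trained networks) are
# cached so the acceptance checks and unit tests reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small two-vertebra phantom for fast FEA tests
fix_small_mesh <- function() fixture("small_mesh", function() {
  build_phantom(phantom_spec(n_vertebrae = 2, vertebra_height = 20,
                             disc_height = 10, mesh_resolution = 8))
})

# the study-scale phantom: an L1-L5-like stack
fix_study_mesh <- function() fixture("study_mesh", function() {
  build_phantom(phantom_spec())
})

# 29 materials x 14 magnitudes = 406 rows, material-level split
fix_dataset <- function() fixture("dataset", function() {
  ds <- build_dataset(fix_study_mesh(), n_materials = 29L, seed = 1L)
  split_and_normalize(ds, seed = 1L)
})

# enlarged calibration dataset, 48 materials x 14 = 672 rows
fix_calib_dataset <- function() fixture("calib_dataset", function() {
  ds <- build_dataset(fix_study_mesh(), n_materials = 48L, seed = 1001L)
  split_and_normalize(ds, seed = 1001L)
})

# the best-architecture network and its fine-tuned refinement
fix_net <- function() fixture("net", function() {
  train_pinn(fix_dataset(), net_config(seed = 1L))
})
fix_net_finetuned <- function() fixture("net_finetuned", function() {
  fine_tune(fix_net(), fix_calib_dataset(), epochs = 1000L)
})

# a tiny synthetic dataset that needs no FEA: random features, targets
# drawn from the sampling ranges (consistent k/mu by construction)
fix_toy_dataset <- function(n = 24L, seed = 7L) {
  mats <- sample_materials(sampling_ranges(), n, seed = seed)
  Y <- t(vapply(mats, spinepinn:::properties_to_targets, numeric(10)))
  set.seed(seed + 1L)
  X <- matrix(stats::rnorm(n * 16), n, 16)
  colnames(X) <- feature_names()
  colnames(Y) <- target_names()
  structure(list(X = X, Y = Y, group = seq_len(n), splits = NULL,
                 stats = NULL, manifest = list(seed = seed)),
            class = "training_dataset")
}

# an internally consistent 10-vector of targets in natural column units
consistent_sample <- function(E_b = 2, nu_b = 0.25, E_d = 2.5, nu_d = 0.46,
                              rho_b = 1500, rho_d = 1100) {
  iso_b <- isotropic_relations(E_b, nu_b)
  iso_d <- isotropic_relations(E_d, nu_d)
  x <- c(E_b, E_d, nu_b, nu_d, iso_b$k, iso_d$k, iso_b$mu, iso_d$mu,
         rho_b, rho_d)
  names(x) <- target_names()
  x
}

# axis-aligned unit cube as a 12-triangle surface, normals outward
fix_cube_surface <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),       # z = 0, normal -z
    c(5, 6, 7), c(6, 8, 7),       # z = 1, normal +z
    c(1, 2, 5), c(2, 6, 5),       # y = 0
    c(3, 7, 4), c(4, 7, 8),       # y = 1
    c(1, 5, 3), c(3, 5, 7),       # x = 0
    c(2, 4, 6), c(4, 8, 6)        # x = 1
  )
  surface_mesh(v, tri)
}
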