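#' Material-property sampling ranges
#'
#' Defaults are the literature-based ranges the training data is drawn
#' from: Young's modulus 10-25 GPa for bone and 1-4.1 MPa for the disc,
#' Poisson's ratio 0.1-0.4 for bone and 0.45-0.48 for the disc. Density is
#' not identifiable from quasi-static linear responses, so it is generated
#' through a latent CT-attenuation draw coupled monotonically to the
#' sampled Young's modulus: `HU` is the linear image of `E` onto
#' `hu_range`, then `rho = c + d * HU` — which makes the density targets a
#' learnable function of the mechanical response. Setting
#' `rho_independent = TRUE` draws HU independently instead, reproducing
#' the ill-posed variant.
#'
#' @param E_bone_GPa,E_disc_MPa,nu_bone,nu_disc Length-2 `(min, max)`
#'   ranges.
#' @param hu_bone,hu_disc Latent attenuation ranges (HU); defaults are the
#'   cortical band 700-2000 HU and a soft-tissue band 40-120 HU.
#' @param c_bone,d_bone,c_disc,d_disc Affine density-calibration
#'   coefficients, `rho = c + d * HU` in kg/m^3.
#' @param rho_independent Draw the latent HU independently of E.
#' @return An object of class `sampling_ranges`.
#' @export
sampling_ranges <- function(E_bone_GPa = c(10, 25), E_disc_MPa = c(1, 4.1),
                            nu_bone = c(0.1, 0.4), nu_disc = c(0.45, 0.48),
                            hu_bone = c(700, 2000), hu_disc = c(40, 120),
                            c_bone = 47, d_bone = 1.22,
                            c_disc = 1000, d_disc = 0.8,
                            rho_independent = FALSE) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2])
      stop(nm, " must be an increasing (min, max) pair")
  }
  chk(E_bone_GPa, "E_bone_GPa"); chk(E_disc_MPa, "E_disc_MPa")
  chk(nu_bone, "nu_bone"); chk(nu_disc, "nu_disc")
  chk(hu_bone, "hu_bone"); chk(hu_disc, "hu_disc")
  if (any(c(E_bone_GPa, E_disc_MPa) <= 0))
    stop("modulus ranges must be strictly positive")
  if (nu_bone[2] >= 0.5 || nu_disc[2] >= 0.5)
    stop("Poisson's ratio must be strictly below 0.5")
  if (nu_bone[1] <= -1 || nu_disc[1] <= -1)
    stop("Poisson's ratio must be strictly above -1")
  structure(list(E_bone_GPa = E_bone_GPa, E_disc_MPa = E_disc_MPa,
                 nu_bone = nu_bone, nu_disc = nu_disc,
                 hu_bone = hu_bone, hu_disc = hu_disc,
                 c_bone = c_bone, d_bone = d_bone,
                 c_disc = c_disc, d_disc = d_disc,
                 rho_independent = rho_independent),
            class = "sampling_ranges")
}

#' The compression load sweep
#'
#' @param magnitudes Prescribed compressions in mm; default is the
#'   0.2-2.8 mm sweep in 0.2 mm increments (14 magnitudes).
#' @param n_steps Quasi-static steps per magnitude (default 10).
#' @return An object of class `load_sweep`.
#' @export
load_sweep <- function(magnitudes = seq(0.2, 2.8, by = 0.2), n_steps = 10L) {
  if (any(magnitudes <= 0)) stop("magnitudes must be strictly positive")
  if (is.unsorted(magnitudes, strictly = TRUE))
    stop("magnitudes must be strictly increasing")
  structure(list(magnitudes = magnitudes, n_steps = as.integer(n_steps)),
            class = "load_sweep")
}

#' Sample material-property sets
#'
#' Independent uniform draws within the ranges; bulk and shear moduli are
#' derived via [isotropic_relations()] and densities via the latent-HU
#' coupling documented in [sampling_ranges()]. Deterministic for a fixed
#' seed.
#'
#' @param ranges A [sampling_ranges()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return List of `n` [material_properties()] objects.
#' @export
sample_materials <- function(ranges, n, seed = 1L) {
  stopifnot(inherits(ranges, "sampling_ranges"))
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  runifr <- function(r) stats::runif(n, r[1], r[2])
  E_b <- runifr(ranges$E_bone_GPa) * 1e9
  E_d <- runifr(ranges$E_disc_MPa) * 1e6
  nu_b <- runifr(ranges$nu_bone)
  nu_d <- runifr(ranges$nu_disc)
  latent <- function(E, Er, hur, independent) {
    if (independent) return(runifr(hur))
    span <- diff(Er)
    frac <- if (span > 0) (E - Er[1]) / span else rep(0.5, length(E))
    hur[1] + frac * diff(hur)
  }
  hu_b <- latent(E_b / 1e9, ranges$E_bone_GPa, ranges$hu_bone,
                 ranges$rho_independent)
  hu_d <- latent(E_d / 1e6, ranges$E_disc_MPa, ranges$hu_disc,
                 ranges$rho_independent)
  rho_b <- ranges$c_bone + ranges$d_bone * hu_b
  rho_d <- ranges$c_disc + ranges$d_disc * hu_d
  lapply(seq_len(n), function(i)
    material_properties(E_b[i], nu_b[i], E_d[i], nu_d[i], rho_b[i], rho_d[i]))
}

#' Build the 16-feature / 10-target training table
#'
#' One row per (material draw x load magnitude). For each material the
#' mesh is solved once at a unit reference magnitude and the response
#' features are scaled exactly to every magnitude of the sweep (the model
#' is linear); targets are the generating properties in natural column
#' units (GPa for bone moduli, MPa for disc moduli). Any failed solve is
#' skipped with a warning and recorded in the manifest.
#'
#' @param mesh A `labeled_tet_mesh`.
#' @param ranges A [sampling_ranges()].
#' @param sweep A [load_sweep()].
#' @param n_materials Number of material draws (default 29; with the
#'   14-magnitude sweep this gives a 406-row table).
#' @param seed Integer seed.
#' @param aggregation Passed to [extract_features()].
#' @return An object of class `training_dataset` with matrices `X`
#'   (n x 16) and `Y` (n x 10), a `manifest` (seed, counts, skipped cases)
#'   and, after [split_and_normalize()], split indices and normalisation
#'   statistics.
#' @export
build_dataset <- function(mesh, ranges = sampling_ranges(),
                          sweep = load_sweep(), n_materials = 29L,
                          seed = 1L, aggregation = "centroid") {
  mats <- sample_materials(ranges, n_materials, seed = seed)
  op <- precompute_operator(mesh)
  nmag <- length(sweep$magnitudes)
  rows_X <- vector("list", n_materials)
  rows_Y <- vector("list", n_materials)
  skipped <- integer(0)
  for (i in seq_len(n_materials)) {
    ref <- tryCatch({
      sol <- assemble_and_solve(mesh, mats[[i]],
                                load_case(1, n_steps = sweep$n_steps),
                                op = op)
      extract_features(sol, mesh, aggregation = aggregation)
    }, error = function(e) {
      warning(sprintf("material draw %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(ref)) { skipped <- c(skipped, i); next }
    rows_X[[i]] <- outer(sweep$magnitudes, ref)
    rows_Y[[i]] <- matrix(properties_to_targets(mats[[i]]), nrow = nmag,
                          ncol = 10L, byrow = TRUE)
  }
  keep <- setdiff(seq_len(n_materials), skipped)
  X <- do.call(rbind, rows_X[keep])
  Y <- do.call(rbind, rows_Y[keep])
  colnames(X) <- feature_names()
  colnames(Y) <- target_names()
  if (anyNA(X) || anyNA(Y)) stop("non-finite entries in dataset")
  structure(list(
    X = X, Y = Y, group = rep(keep, each = nmag),
    splits = NULL, stats = NULL,
    manifest = list(seed = seed, n_materials = n_materials,
                    magnitudes = sweep$magnitudes, skipped = skipped,
                    aggregation = aggregation)
  ), class = "training_dataset")
}

#' @export
print.training_dataset <- function(x, ...) {
  cat(sprintf("training_dataset: %d rows, %d features, %d targets%s\n",
              nrow(x$X), ncol(x$X), ncol(x$Y),
              if (is.null(x$splits)) " (unsplit)" else
                sprintf(" (train/val/test = %d/%d/%d)",
                        length(x$splits$train), length(x$splits$val),
                        length(x$splits$test))))
  invisible(x)
}

# largest-remainder apportionment of n rows into length(fractions) groups
largest_remainder_sizes <- function(n, fractions) {
  exact <- n * fractions
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    o <- order(exact - sizes, decreasing = TRUE)
    sizes[o[seq_len(rem)]] <- sizes[o[seq_len(rem)]] + 1
  }
  as.integer(sizes)
}

#' Split a dataset and fit normalisation statistics
#'
#' Apportions the dataset into train/validation/test by largest-remainder
#' rounding of the fractions and a seeded permutation. With
#' `by = "material"` (the default when the dataset records which material
#' draw generated each row) whole materials are assigned to one split:
#' rows of the same material under different load magnitudes are exact
#' scalar multiples of each other, so a row-level split would leak every
#' test material into training and overstate generalisation.
#' `by = "row"` gives the plain row-level split. Per-column z-score
#' statistics (mean, sd) for both features and targets are fitted on the
#' training split only; validation and test rows never influence them.
#' Near-constant columns fall back to unit scale.
#'
#' @param ds A [build_dataset()] result.
#' @param fractions Length-3 positive fractions summing to 1.
#' @param seed Integer seed for the permutation.
#' @param by Split unit: `"material"` (default when available) or
#'   `"row"`.
#' @return The dataset with `splits` (index vectors `train`, `val`,
#'   `test`) and `stats` (`x_mean`, `x_sd`, `y_mean`, `y_sd`) filled in.
#' @export
split_and_normalize <- function(ds, fractions = c(0.7, 0.15, 0.15),
                                seed = 1L, by = NULL) {
  stopifnot(inherits(ds, "training_dataset"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be 3 positive numbers summing to 1")
  if (is.null(by)) by <- if (is.null(ds$group)) "row" else "material"
  by <- match.arg(by, c("row", "material"))
  if (by == "material" && is.null(ds$group))
    stop("dataset does not record material groups; use by = \"row\"")
  set.seed(seed)
  if (by == "material") {
    groups <- unique(ds$group)
    sizes <- largest_remainder_sizes(length(groups), fractions)
    if (any(sizes < 1L)) stop("a split would contain fewer than 1 material")
    perm <- sample(groups)
    gsplit <- list(train = perm[seq_len(sizes[1])],
                   val = perm[sizes[1] + seq_len(sizes[2])],
                   test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
    ds$splits <- lapply(gsplit, function(g) which(ds$group %in% g))
  } else {
    n <- nrow(ds$X)
    sizes <- largest_remainder_sizes(n, fractions)
    if (any(sizes < 1L)) stop("a split would contain fewer than 1 sample")
    perm <- sample.int(n)
    ds$splits <- list(train = sort(perm[seq_len(sizes[1])]),
                      val = sort(perm[sizes[1] + seq_len(sizes[2])]),
                      test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
  }
  tr <- ds$splits$train
  safe_sd <- function(m) {
    s <- apply(m, 2, stats::sd)
    ifelse(is.finite(s) & s > 1e-12, s, 1)
  }
  x_sd <- safe_sd(ds$X[tr, , drop = FALSE])
  # Features whose variation is at numerical-precision level relative to
  # the dominant feature of the same physical unit group (force,
  # displacement, stress, strain) carry no mechanical information — e.g.
  # shear responses of a symmetric phantom under axial load, which are
  # pure solver round-off. Flooring their scale inside the group keeps
  # z-scoring from amplifying that round-off into a pseudo-signal the
  # network would latch onto.
  if (identical(colnames(ds$X), feature_names())) {
    for (grp in list(2:4, 5:10, 11:16)) {
      floor_sd <- 1e-6 * max(x_sd[grp])
      x_sd[grp] <- pmax(x_sd[grp], floor_sd)
    }
  }
  ds$stats <- list(x_mean = colMeans(ds$X[tr, , drop = FALSE]),
                   x_sd = x_sd,
                   y_mean = colMeans(ds$Y[tr, , drop = FALSE]),
                   y_sd = safe_sd(ds$Y[tr, , drop = FALSE]))
  ds
}

# z-score helpers; de-normalisation round-trips to machine precision
normalize_cols <- function(m, mean, sd) sweep(sweep(m, 2, mean), 2, sd, "/")
denormalize_cols <- function(m, mean, sd) sweep(sweep(m, 2, sd, "*"), 2, mean, "+")

#' Write / read a training dataset as CSV
#'
#' The CSV carries the fixed 16 + 10 column header (features then
#' targets); written with full precision so identical seeds produce
#' byte-identical files.
#'
#' @param ds A `training_dataset`.
#' @param path Output path.
#' @return `path` invisibly, or for the reader a `training_dataset`
#'   (unsplit).
#' @export
write_dataset_csv <- function(ds, path) {
  df <- cbind(as.data.frame(ds$X), as.data.frame(ds$Y))
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  fn <- feature_names(); tn <- target_names()
  if (!all(c(fn, tn) %in% names(df)))
    stop("CSV does not carry the canonical 16+10 column header")
  structure(list(X = as.matrix(df[fn]), Y = as.matrix(df[tn]),
                 splits = NULL, stats = NULL,
                 manifest = list(source = path)),
            class = "training_dataset")
}
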