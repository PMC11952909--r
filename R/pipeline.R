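default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    verbose = TRUE,
    phantom = list(n_vertebrae = 5L, vertebra_height_mm = 28,
                   disc_height_mm = 10, cross_section = "cylinder",
                   radius_mm = 20, half_width_mm = c(20, 20),
                   mesh_resolution_mm = 7),
    dataset = list(n_materials = 29L, n_materials_calibration = 48L,
                   magnitudes_mm = seq(0.2, 2.8, by = 0.2), n_steps = 10L,
                   fractions = c(0.7, 0.15, 0.15),
                   E_bone_GPa = c(10, 25), E_disc_MPa = c(1, 4.1),
                   nu_bone = c(0.1, 0.4), nu_disc = c(0.45, 0.48),
                   aggregation = "centroid"),
    net = list(hidden = c(64L, 32L, 16L), activation = "tanh",
               lambda1 = 0.1, lambda2 = 0.1, lr = 1e-3, epochs = 1500L,
               patience = 200L, input_noise = 0.05, finetune_epochs = 800L,
               sweep = FALSE, sweep_epochs = 400L),
    loop = list(max_iter = 10L, tol = 1e-3, load_magnitude_mm = 1.4,
                update = "anchored", eta = 0.7, n_ground_truths = 5L)
  )
}

deep_merge <- function(base, user, path = character()) {
  for (nm in names(user)) {
    here <- c(path, nm)
    if (!nm %in% names(base))
      stop("unknown configuration key: ", paste(here, collapse = "."))
    if (is.list(base[[nm]]) && !is.null(user[[nm]])) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", paste(here, collapse = "."),
             " must be a mapping")
      base[[nm]] <- deep_merge(base[[nm]], user[[nm]], here)
    } else if (!is.null(user[[nm]])) {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML configuration (or accepts a list), rejects unknown keys,
#' injects defaults for everything unspecified, checks value ranges
#' (strictly positive sizes, Poisson's ratio strictly below 0.5), and
#' attaches the SI equivalents of the unit-bearing fields (`*_mm` in
#' metres, modulus ranges in Pa) as the `si` element. An empty file yields
#' the fully defaulted configuration.
#'
#' @param path Path to a YAML file, or a named list of overrides, or
#'   `NULL` for pure defaults.
#' @return A validated configuration list of class `run_config`.
#' @export
validate_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
  else if (is.character(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  } else if (is.list(path)) path
  else stop("path must be a file path, a list, or NULL")
  cfg <- deep_merge(default_run_config(), user)

  with(cfg$phantom, {
    if (n_vertebrae < 1) stop("phantom.n_vertebrae must be >= 1 (got ", n_vertebrae, ")")
    if (vertebra_height_mm <= 0 || disc_height_mm <= 0 || mesh_resolution_mm <= 0)
      stop("phantom heights and mesh_resolution_mm must be strictly positive")
  })
  rng <- cfg$dataset
  for (nm in c("E_bone_GPa", "E_disc_MPa", "nu_bone", "nu_disc")) {
    r <- rng[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop("dataset.", nm, " must be an increasing (min, max) pair")
  }
  if (rng$nu_bone[2] >= 0.5 || rng$nu_disc[2] >= 0.5)
    stop("dataset Poisson-ratio upper bounds must be strictly below 0.5 ",
         "(incompressible limit)")
  if (any(rng$magnitudes_mm <= 0))
    stop("dataset.magnitudes_mm must be strictly positive")
  if (abs(sum(rng$fractions) - 1) > 1e-9)
    stop("dataset.fractions must sum to 1")
  if (cfg$loop$tol <= 0) stop("loop.tol must be positive")

  cfg$si <- list(
    vertebra_height_m = cfg$phantom$vertebra_height_mm * 1e-3,
    disc_height_m = cfg$phantom$disc_height_mm * 1e-3,
    radius_m = cfg$phantom$radius_mm * 1e-3,
    mesh_resolution_m = cfg$phantom$mesh_resolution_mm * 1e-3,
    magnitudes_m = cfg$dataset$magnitudes_mm * 1e-3,
    E_bone_Pa = cfg$dataset$E_bone_GPa * 1e9,
    E_disc_Pa = cfg$dataset$E_disc_MPa * 1e6,
    load_magnitude_m = cfg$loop$load_magnitude_mm * 1e-3
  )
  class(cfg) <- "run_config"
  cfg
}

#' Run the full phantom-to-calibration pipeline
#'
#' Chains every stage: phantom generation, dataset building and
#' normalisation, network training (optionally the full architecture
#' sweep), fine-tuning on an enlarged calibration dataset, and the hybrid
#' calibration loop on freshly drawn ground truths. When `output_dir` is
#' set, a self-contained results bundle is written: the dataset CSV, the
#' sweep table, the network checkpoint, the convergence report (JSON) and
#' a summary with every seed and the resolved configuration.
#'
#' @param cfg A [validate_config()] result (or anything it accepts).
#' @return A `results_bundle` list: `mesh`, `dataset`, `sweep` (or NULL),
#'   `net`, `records`, `summary`.
#' @export
run_pipeline <- function(cfg = validate_config()) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  t0 <- Sys.time()

  say("[phantom] building %d-vertebra phantom", cfg$phantom$n_vertebrae)
  spec <- phantom_spec(n_vertebrae = cfg$phantom$n_vertebrae,
                       vertebra_height = cfg$phantom$vertebra_height_mm,
                       disc_height = cfg$phantom$disc_height_mm,
                       cross_section = cfg$phantom$cross_section,
                       radius = cfg$phantom$radius_mm,
                       half_width = cfg$phantom$half_width_mm,
                       mesh_resolution = cfg$phantom$mesh_resolution_mm,
                       seed = cfg$seed)
  mesh <- build_phantom(spec)

  ranges <- sampling_ranges(E_bone_GPa = cfg$dataset$E_bone_GPa,
                            E_disc_MPa = cfg$dataset$E_disc_MPa,
                            nu_bone = cfg$dataset$nu_bone,
                            nu_disc = cfg$dataset$nu_disc)
  sweep_def <- load_sweep(cfg$dataset$magnitudes_mm, cfg$dataset$n_steps)
  say("[dataset] %d materials x %d magnitudes", cfg$dataset$n_materials,
      length(sweep_def$magnitudes))
  ds <- build_dataset(mesh, ranges, sweep_def,
                      n_materials = cfg$dataset$n_materials,
                      seed = cfg$seed, aggregation = cfg$dataset$aggregation)
  ds <- split_and_normalize(ds, cfg$dataset$fractions, seed = cfg$seed)

  base_cfg <- net_config(hidden = cfg$net$hidden,
                         activation = cfg$net$activation,
                         lambda1 = cfg$net$lambda1, lambda2 = cfg$net$lambda2,
                         lr = cfg$net$lr, epochs = cfg$net$epochs,
                         patience = cfg$net$patience,
                         input_noise = cfg$net$input_noise, seed = cfg$seed)
  sweep_tbl <- NULL
  if (isTRUE(cfg$net$sweep)) {
    say("[pinn] architecture sweep (%d cases)", length(sweep_architectures()))
    swcfg <- base_cfg; swcfg$epochs <- as.integer(cfg$net$sweep_epochs)
    sweep_tbl <- architecture_sweep(ds, base_cfg = swcfg)
  }
  say("[pinn] training [%s]", paste(cfg$net$hidden, collapse = "-"))
  net <- train_pinn(ds, base_cfg)

  say("[pinn] fine-tuning on enlarged calibration dataset (%d materials)",
      cfg$dataset$n_materials_calibration)
  calib <- build_dataset(mesh, ranges, sweep_def,
                         n_materials = cfg$dataset$n_materials_calibration,
                         seed = cfg$seed + 1000L,
                         aggregation = cfg$dataset$aggregation)
  calib <- split_and_normalize(calib, cfg$dataset$fractions,
                               seed = cfg$seed + 1000L)
  net <- fine_tune(net, calib, epochs = cfg$net$finetune_epochs)

  say("[calibrate] hybrid loop on %d ground truths", cfg$loop$n_ground_truths)
  truths <- sample_materials(ranges, cfg$loop$n_ground_truths,
                             seed = cfg$seed + 2000L)
  lcfg <- loop_config(max_iter = cfg$loop$max_iter, tol = cfg$loop$tol,
                      load_magnitude = cfg$loop$load_magnitude_mm,
                      update = cfg$loop$update, eta = cfg$loop$eta,
                      aggregation = cfg$dataset$aggregation)
  records <- lapply(truths, function(tr)
    run_loop(mesh, net, lcfg, ground_truth = tr))
  reports <- lapply(records, report_final)
  err_E <- t(vapply(reports, function(r)
    r$error_rel[c("E_bone_GPa", "E_disc_MPa")], numeric(2)))

  summary <- list(
    seed = cfg$seed,
    n_rows_train = nrow(ds$X), n_rows_calibration = nrow(calib$X),
    accuracies = as.list(net$metrics),
    finetune = lapply(net$finetune, as.list),
    recovery_median_rel_err = list(
      E_bone = stats::median(err_E[, 1]),
      E_disc = stats::median(err_E[, 2])),
    loop_converged = vapply(records, `[[`, logical(1), "converged"),
    loop_iterations = vapply(records, `[[`, integer(1), "n_iterations"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$output_dir, f)
    write_dataset_csv(ds, out("dataset.csv"))
    write_dataset_csv(calib, out("dataset_calibration.csv"))
    if (!is.null(sweep_tbl))
      utils::write.csv(sweep_tbl, out("sweep.csv"), row.names = FALSE)
    write_checkpoint(net, out("net.ckpt"))
    write_vtk(mesh, out("mesh.vtk"))
    jsonlite::write_json(
      list(summary = summary,
           records = lapply(records, function(r)
             list(iterates = r$iterates, rel_steps = r$rel_steps,
                  errors = r$errors, converged = r$converged))),
      out("convergence.json"), auto_unbox = TRUE, digits = NA)
    cfg_echo <- unclass(cfg); cfg_echo$si <- NULL
    yaml::write_yaml(cfg_echo, out("config_resolved.yaml"))
  }

  structure(list(mesh = mesh, dataset = ds, calibration = calib,
                 sweep = sweep_tbl, net = net, records = records,
                 reports = reports, summary = summary, config = cfg),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  s <- x$summary
  cat("results_bundle\n")
  cat(sprintf("  dataset rows: %d (train) / %d (calibration)\n",
              s$n_rows_train, s$n_rows_calibration))
  cat(sprintf("  accuracy (train/val/test): %.2f%% / %.2f%% / %.2f%%\n",
              s$accuracies$train, s$accuracies$val, s$accuracies$test))
  cat(sprintf("  recovery median rel. err.: E_bone %.2f%%, E_disc %.2f%%\n",
              100 * s$recovery_median_rel_err$E_bone,
              100 * s$recovery_median_rel_err$E_disc))
  cat(sprintf("  loops converged: %d/%d\n", sum(s$loop_converged),
              length(s$loop_converged)))
  invisible(x)
}
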