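#' Configuration of the FEA/network fixed-point loop
#'
#' @param max_iter Maximum loop iterations (default 10).
#' @param tol Relative step tolerance on the normalised property vector
#'   (default 1e-3): the loop stops when
#'   `||x_{n+1} - x_n|| / ||x_n|| <= tol`.
#' @param load_magnitude Compression (mm) simulated inside the loop;
#'   default 1.4 mm, the mid-sweep magnitude.
#' @param initial Optional named 10-vector of starting properties in
#'   natural column units; when `NULL` the loop starts from the network's
#'   prediction on the observed response (if one is supplied) or must be
#'   given explicitly.
#' @param update Update rule. `"anchored"` (default) keeps the observed
#'   response in every cycle,
#'   `x_{n+1} = x_n + eta * (g(y_obs) - g(f(x_n)))` with `g` the network
#'   prediction: its fixed point makes the simulated response agree with
#'   the observation under the network's reading, and its
#'   error-propagation operator is `I - eta * J` with `J` the Jacobian of
#'   the network-FEA composite, which is contractive precisely when the
#'   network approximately inverts the simulator. `"direct"` is the bare
#'   re-substitution `x_{n+1} = g(f(x_n))`, whose fixed point is
#'   independent of any observation; it is retained for analysing the
#'   loop itself.
#' @param eta Relaxation factor in (0, 1] for the anchored update;
#'   under-relaxation (default 0.7) buys stability margin against local
#'   fluctuations of the composite Jacobian.
#' @param aggregation Feature aggregation, as in [extract_features()].
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(max_iter = 10L, tol = 1e-3, load_magnitude = 1.4,
                        initial = NULL, update = c("anchored", "direct"),
                        eta = 0.7, aggregation = "centroid") {
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  if (load_magnitude <= 0) stop("load_magnitude must be positive")
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 load_magnitude = load_magnitude, initial = initial,
                 update = match.arg(update), eta = eta,
                 aggregation = aggregation),
            class = "loop_config")
}

#' Iterate a fixed-point map with convergence bookkeeping
#'
#' Repeatedly applies `step_fn` to a property vector, recording iterates,
#' relative step sizes in a user-supplied norm, and — when a ground truth
#' is known — errors and contraction ratios `||e_{n+1}|| / ||e_n||`. This
#' is the bare iteration engine behind [run_loop()]; it is exported so
#' that constructed maps (exact inverses, linear contraction stubs) can be
#' analysed with the same bookkeeping.
#'
#' @param step_fn Function mapping a named 10-vector to the next iterate.
#' @param x0 Starting vector.
#' @param max_iter,tol As in [loop_config()].
#' @param norm_fn Norm used for steps and errors (default 2-norm).
#' @param ground_truth Optional true property vector for error tracking.
#' @return An object of class `convergence_record`: `iterates` (list,
#'   `x0` first), `steps`, `rel_steps`, `errors`, `ratios`, `converged`,
#'   `n_iterations`.
#' @export
iterate_map <- function(step_fn, x0, max_iter = 10L, tol = 1e-3,
                        norm_fn = function(v) sqrt(sum(v^2)),
                        ground_truth = NULL) {
  iterates <- list(x0)
  steps <- numeric(0); rel_steps <- numeric(0)
  errors <- if (is.null(ground_truth)) NULL else norm_fn(x0 - ground_truth)
  converged <- FALSE
  x <- x0
  for (n in seq_len(max_iter)) {
    x_next <- step_fn(x)
    if (any(!is.finite(x_next)))
      stop("non-finite iterate at loop iteration ", n)
    iterates[[n + 1L]] <- x_next
    st <- norm_fn(x_next - x)
    steps <- c(steps, st)
    denom <- norm_fn(x)
    rel <- if (denom > 0) st / denom else st
    rel_steps <- c(rel_steps, rel)
    if (!is.null(ground_truth))
      errors <- c(errors, norm_fn(x_next - ground_truth))
    x <- x_next
    if (rel <= tol) { converged <- TRUE; break }
  }
  ratios <- if (!is.null(errors) && length(errors) >= 2L) {
    r <- errors[-1] / errors[-length(errors)]
    r[is.finite(r)]
  } else if (length(steps) >= 2L) {
    r <- steps[-1] / steps[-length(steps)]
    r[is.finite(r)]
  } else numeric(0)
  structure(list(iterates = iterates, steps = steps, rel_steps = rel_steps,
                 errors = errors, ratios = ratios, converged = converged,
                 n_iterations = length(steps)),
            class = "convergence_record")
}

#' @export
print.convergence_record <- function(x, ...) {
  cat(sprintf("convergence_record: %d iterations, converged: %s\n",
              x$n_iterations, x$converged))
  if (length(x$rel_steps))
    cat("  relative steps:", paste(sprintf("%.3g", x$rel_steps), collapse = " "), "\n")
  invisible(x)
}

#' Run the hybrid FEA/network calibration loop
#'
#' Iteratively couples the forward FEA map `f` (simulate the phantom with
#' the current property estimate, extract the 16 response features) with
#' the network prediction `g` until the property estimate stabilises.
#' When a ground truth is supplied it stands in for the measured
#' specimen: its simulated response is the observed data, the loop starts
#' from the network's prediction on that observation (unless
#' `cfg$initial` overrides it), and errors/contraction ratios are tracked
#' against it. The default anchored update re-uses the observed response
#' in every cycle (see [loop_config()]); the `"direct"` rule is the bare
#' re-substitution `x_{n+1} = g(f(x_n))`. Predicted Poisson ratios
#' falling outside the admissible open interval are clamped before
#' re-simulation and the events are recorded.
#'
#' @param mesh A `labeled_tet_mesh`.
#' @param net A trained `pinn_net`, or any function mapping a 16-feature
#'   vector to a 10-vector of properties (useful for oracle stubs).
#' @param cfg A [loop_config()].
#' @param ground_truth Optional [material_properties()] of the simulated
#'   specimen.
#' @return A `convergence_record` with additional fields `responses`
#'   (feature vectors per iteration), `observed`, `clamp_events` and
#'   `final` (the last iterate).
#' @export
run_loop <- function(mesh, net, cfg = loop_config(), ground_truth = NULL) {
  stopifnot(inherits(cfg, "loop_config"))
  op <- precompute_operator(mesh)
  load <- load_case(cfg$load_magnitude)
  clamp_events <- character(0)
  log_clamp <- function(msg) clamp_events <<- c(clamp_events, msg)

  predictor <- if (is.function(net)) net else {
    function(feat) drop(predict(net, feat))
  }
  simulate <- function(xvec) {
    mat <- targets_to_properties(xvec, clamp_log = log_clamp)
    sol <- assemble_and_solve(mesh, mat, load, op = op)
    extract_features(sol, mesh, aggregation = cfg$aggregation)
  }

  responses <- list()
  repredict <- function(x) {
    feat <- simulate(x)
    responses[[length(responses) + 1L]] <<- feat
    out <- predictor(feat)
    names(out) <- target_names()
    out
  }

  # scale-free norm: 2-norm on z-scored properties when stats available
  norm_fn <- if (!is.function(net) && !is.null(net$stats)) {
    sd <- net$stats$y_sd
    function(v) sqrt(sum((v / sd)^2))
  } else function(v) sqrt(sum(v^2))

  truth_vec <- NULL
  observed <- NULL
  if (!is.null(ground_truth)) {
    stopifnot(inherits(ground_truth, "material_properties"))
    truth_vec <- properties_to_targets(ground_truth)
    observed <- simulate(truth_vec)
  }
  anchor <- if (!is.null(observed)) {
    v <- predictor(observed); names(v) <- target_names(); v
  } else NULL
  x0 <- if (!is.null(cfg$initial)) {
    v <- cfg$initial; names(v) <- target_names(); v
  } else if (!is.null(anchor)) {
    anchor
  } else {
    stop("no starting point: supply cfg$initial or a ground truth")
  }
  step_fn <- if (cfg$update == "anchored") {
    if (is.null(anchor))
      stop("anchored update needs an observed response (supply a ground ",
           "truth) ; use update = \"direct\" otherwise")
    function(x) x + cfg$eta * (anchor - repredict(x))
  } else {
    repredict
  }

  rec <- iterate_map(step_fn, x0, max_iter = cfg$max_iter, tol = cfg$tol,
                     norm_fn = norm_fn, ground_truth = truth_vec)
  rec$responses <- responses
  rec$observed <- observed
  rec$clamp_events <- clamp_events
  # converged: the last iterate; otherwise the most self-consistent one
  # (the iterate with the smallest fixed-point residual, i.e. step size)
  rec$final <- if (rec$converged || length(rec$steps) == 0L)
    rec$iterates[[length(rec$iterates)]]
  else rec$iterates[[which.min(rec$steps)]]
  rec$ground_truth <- truth_vec
  rec
}

#' Estimate the empirical contraction factor
#'
#' Geometric mean of the successive ratios recorded in a convergence
#' record: error-norm ratios `||e_{n+1}|| / ||e_n||` when a ground truth
#' was tracked, step-size ratios otherwise. The leading third of the
#' ratios is discarded as transient when at least six are available, so
#' the estimate reflects the asymptotic rate (for a linearised iteration,
#' the spectral radius of the error-propagation operator) rather than the
#' decay of sub-dominant error components. An estimate of 1 or more flags
#' divergence.
#'
#' @param record A `convergence_record`.
#' @return Scalar `rho_estimate` with attribute `divergent`.
#' @export
estimate_contraction <- function(record) {
  stopifnot(inherits(record, "convergence_record"))
  r <- record$ratios
  if (length(r) < 1L)
    stop("too few iterates to estimate a contraction factor (need >= 3 ",
         "iterates, or >= 2 errors with a known ground truth)")
  if (length(r) >= 6L) r <- r[-seq_len(floor(length(r) / 3))]
  rho <- exp(mean(log(pmax(r, .Machine$double.xmin))))
  structure(rho, divergent = rho >= 1)
}

#' Report the calibrated properties and consistency residuals
#'
#' Returns the final iterate as a [material_properties()] object together
#' with the relative elasticity-consistency residuals
#' `|k - E/(3(1-2nu))| / k` and `|mu - E/(2(1+nu))| / mu` of the raw
#' network prediction for bone and disc. The residuals are diagnostics of
#' how well the soft physics penalty was respected; they are reported,
#' never enforced. A non-converged record yields the best (last) iterate
#' with `converged = FALSE`.
#'
#' @param record A `convergence_record` from [run_loop()].
#' @return List with `properties` (a `material_properties` built from the
#'   final iterate), `estimate` (the raw 10-vector), `residuals` (named:
#'   bone_bulk, bone_shear, disc_bulk, disc_shear), `converged`, and
#'   `error_rel` per property when a ground truth was tracked.
#' @export
report_final <- function(record) {
  stopifnot(inherits(record, "convergence_record"))
  x <- record$final
  if (is.null(x)) x <- record$iterates[[length(record$iterates)]]
  if (!record$converged)
    warning("loop did not converge; reporting the last iterate")
  res <- c(
    bone_bulk = abs(x[["k_bone_GPa"]] -
                      x[["E_bone_GPa"]] / (3 * (1 - 2 * x[["nu_bone"]]))) /
      abs(x[["k_bone_GPa"]]),
    bone_shear = abs(x[["mu_bone_GPa"]] -
                       x[["E_bone_GPa"]] / (2 * (1 + x[["nu_bone"]]))) /
      abs(x[["mu_bone_GPa"]]),
    disc_bulk = abs(x[["k_disc_MPa"]] -
                      x[["E_disc_MPa"]] / (3 * (1 - 2 * x[["nu_disc"]]))) /
      abs(x[["k_disc_MPa"]]),
    disc_shear = abs(x[["mu_disc_MPa"]] -
                       x[["E_disc_MPa"]] / (2 * (1 + x[["nu_disc"]]))) /
      abs(x[["mu_disc_MPa"]])
  )
  out <- list(properties = targets_to_properties(x), estimate = x,
              residuals = res, converged = record$converged)
  if (!is.null(record$ground_truth)) {
    out$error_rel <- abs(x - record$ground_truth) / abs(record$ground_truth)
  }
  out
}
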