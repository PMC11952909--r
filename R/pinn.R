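#' Network configuration
#'
#' Multilayer-perceptron hyperparameters for the material-property
#' regressor. The default hidden architecture `[64, 32, 16]` is the
#' best-performing case of the architecture sweep; `lambda1` and `lambda2`
#' weight the bulk-modulus and shear-modulus consistency penalties of the
#' physics-informed loss.
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param activation Hidden nonlinearity. The default `"tanh"` gives the
#'   smooth derivatives the hybrid calibration loop relies on; `"relu"`
#'   trains the same but yields a piecewise-constant inverse Jacobian.
#' @param lambda1,lambda2 Non-negative physics-penalty weights.
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size; `Inf` (default) trains full-batch.
#' @param patience Early-stopping patience on the validation loss, in
#'   epochs; `Inf` disables early stopping.
#' @param input_noise Standard deviation (in z-score units) of Gaussian
#'   jitter added to the training features each epoch. This smoothness
#'   regularisation bounds the derivative of the learned inverse map:
#'   response directions whose signal lies below the noise floor stop
#'   being amplified, which is what keeps the hybrid FEA/network
#'   fixed-point iteration contractive (the spectral-radius condition of
#'   the error-propagation analysis). Set to 0 for a plain fit.
#' @param seed Integer seed for initialisation and batching.
#' @return An object of class `net_config`.
#' @export
net_config <- function(hidden = c(64L, 32L, 16L), activation = c("tanh", "relu"),
                       lambda1 = 0.1, lambda2 = 0.1, lr = 1e-3,
                       epochs = 2000L, batch_size = Inf, patience = 200L,
                       input_noise = 0.05, seed = 1L) {
  activation <- match.arg(activation)
  if (any(hidden < 1)) stop("hidden widths must be positive")
  if (lambda1 < 0 || lambda2 < 0) stop("penalty weights must be non-negative")
  if (lr < 0) stop("learning rate must be non-negative")
  if (input_noise < 0) stop("input_noise must be non-negative")
  structure(list(hidden = as.integer(hidden), activation = activation,
                 lambda1 = lambda1, lambda2 = lambda2, lr = lr,
                 epochs = as.integer(epochs), batch_size = batch_size,
                 patience = patience, input_noise = input_noise,
                 seed = as.integer(seed)),
            class = "net_config")
}

#' The architecture cases of the sweep
#'
#' @return List of the 11 hidden-layer configurations explored by
#'   [architecture_sweep()].
#' @export
sweep_architectures <- function() {
  list(c(16L), c(32L), c(64L), c(16L, 8L), c(16L, 16L), c(32L, 16L),
       c(32L, 32L), c(64L, 32L), c(64L, 64L), c(64L, 32L, 16L),
       c(128L, 64L, 32L))
}

# He-uniform initialisation of all layers, seeded
init_params <- function(n_in, hidden, n_out, seed) {
  set.seed(seed)
  widths <- c(n_in, hidden, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(widths) - 1L)) {
    lim <- sqrt(6 / widths[l])
    W[[l]] <- matrix(stats::runif(widths[l] * widths[l + 1], -lim, lim),
                     widths[l], widths[l + 1])
    b[[l]] <- numeric(widths[l + 1])
  }
  list(W = W, b = b)
}

act_fun <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else tanh(z)
}
act_grad <- function(a, activation) {
  if (activation == "relu") (a > 0) * 1 else 1 - a^2
}

# forward pass keeping activations for backprop; X is n x n_in (normalised)
mlp_forward <- function(params, X, activation) {
  L <- length(params$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    Z <- sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], "+")
    A[[l + 1L]] <- act_fun(Z, activation)
  }
  A[[L + 1L]] <- sweep(A[[L]] %*% params$W[[L]], 2, params$b[[L]], "+")
  A
}

# column indices of the target vector
TGT <- list(E_b = 1L, E_d = 2L, nu_b = 3L, nu_d = 4L,
            k_b = 5L, k_d = 6L, mu_b = 7L, mu_d = 8L)

NU_CLAMP_EPS <- 1e-6

# Consistency residuals and their derivatives for one material group.
# Values are in natural column units; nu is clamped into the admissible
# open interval for evaluation (subgradient zero through the clamp).
group_residuals <- function(E, nu, k, mu) {
  clamped <- nu >= 0.5 - NU_CLAMP_EPS | nu <= -1 + NU_CLAMP_EPS
  nu_c <- pmin(pmax(nu, -1 + NU_CLAMP_EPS), 0.5 - NU_CLAMP_EPS)
  f1 <- E / (3 * (1 - 2 * nu_c))   # consistent bulk modulus
  f2 <- E / (2 * (1 + nu_c))       # consistent shear modulus
  list(r1 = k - f1, r2 = mu - f2,
       d_f1_dE = 1 / (3 * (1 - 2 * nu_c)),
       d_f1_dnu = ifelse(clamped, 0, 2 * E / (3 * (1 - 2 * nu_c)^2)),
       d_f2_dE = 1 / (2 * (1 + nu_c)),
       d_f2_dnu = ifelse(clamped, 0, -E / (2 * (1 + nu_c)^2)),
       n_clamped = sum(clamped))
}

#' Physics-informed loss
#'
#' Mean squared error over the ten outputs plus the two elasticity
#' consistency penalties,
#' `lambda1 * mean |k - E / (3 (1 - 2 nu))|` and
#' `lambda2 * mean |mu - E / (2 (1 + nu))|`,
#' each evaluated separately for the bone and disc parameter groups and
#' averaged over the two groups. Inputs are in physical column units (the
#' identities are unit-invariant within a group). Predicted Poisson ratios
#' at or beyond the incompressible limit are clamped to `0.5 - 1e-6`
#' inside the penalty (the number of clamped entries is reported, not
#' raised).
#'
#' @param pred,target Numeric n x 10 matrices (or length-10 vectors) in the
#'   canonical target order, physical units.
#' @param lambda1,lambda2 Penalty weights.
#' @return Scalar loss with attributes `mse`, `c1`, `c2` (the three terms;
#'   the total is exactly their weighted sum) and `n_clamped`.
#' @export
pinn_loss <- function(pred, target, lambda1 = 0.1, lambda2 = 0.1) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1)
  if (is.null(dim(target))) target <- matrix(target, nrow = 1)
  stopifnot(ncol(pred) == 10L, ncol(target) == 10L,
            nrow(pred) == nrow(target))
  mse <- mean((pred - target)^2)
  gb <- group_residuals(pred[, TGT$E_b], pred[, TGT$nu_b],
                        pred[, TGT$k_b], pred[, TGT$mu_b])
  gd <- group_residuals(pred[, TGT$E_d], pred[, TGT$nu_d],
                        pred[, TGT$k_d], pred[, TGT$mu_d])
  c1 <- (mean(abs(gb$r1)) + mean(abs(gd$r1))) / 2
  c2 <- (mean(abs(gb$r2)) + mean(abs(gd$r2))) / 2
  structure(mse + lambda1 * c1 + lambda2 * c2,
            mse = mse, c1 = c1, c2 = c2,
            n_clamped = gb$n_clamped + gd$n_clamped)
}

#' Mean bounded-relative-error accuracy
#'
#' `100 * mean(max(0, 1 - |pred - target| / |target|))` over all samples
#' and outputs: 100% for perfect prediction, 90% when every output is off
#' by 10%, floored at zero per entry so gross outliers cannot drive the
#' score negative.
#'
#' @param pred,target Numeric matrices or vectors of equal shape with
#'   non-zero targets.
#' @return Percentage in `[0, 100]`.
#' @export
accuracy <- function(pred, target) {
  stopifnot(length(pred) == length(target))
  100 * mean(pmax(0, 1 - abs(pred - target) / abs(target)))
}

# Relative consistency residuals |k - E/(3(1-2nu))| / k etc., averaged
# over the bone and disc groups; the diagnostic that the physics penalty
# is meant to shrink.
constraint_residuals <- function(pred) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1)
  gb <- group_residuals(pred[, TGT$E_b], pred[, TGT$nu_b],
                        pred[, TGT$k_b], pred[, TGT$mu_b])
  gd <- group_residuals(pred[, TGT$E_d], pred[, TGT$nu_d],
                        pred[, TGT$k_d], pred[, TGT$mu_d])
  c(bulk = mean(c(abs(gb$r1) / abs(pred[, TGT$k_b]),
                  abs(gd$r1) / abs(pred[, TGT$k_d]))),
    shear = mean(c(abs(gb$r2) / abs(pred[, TGT$mu_b]),
                   abs(gd$r2) / abs(pred[, TGT$mu_d]))))
}

# Training loss and gradient w.r.t. the normalised predictions.
# MSE is computed on normalised columns (comparable scales across GPa/MPa
# columns); the physics penalties are computed on de-normalised values in
# natural column units. Returns list(loss, grad, terms).
train_loss_grad <- function(pred_n, Y_n, stats, lambda1, lambda2) {
  n <- nrow(pred_n)
  mse <- mean((pred_n - Y_n)^2)
  grad <- 2 * (pred_n - Y_n) / (n * ncol(pred_n))
  c1 <- c2 <- 0
  if (lambda1 > 0 || lambda2 > 0) {
    P <- denormalize_cols(pred_n, stats$y_mean, stats$y_sd)
    gpen <- matrix(0, n, 10L)
    for (g in list(c(TGT$E_b, TGT$nu_b, TGT$k_b, TGT$mu_b),
                   c(TGT$E_d, TGT$nu_d, TGT$k_d, TGT$mu_d))) {
      gr <- group_residuals(P[, g[1]], P[, g[2]], P[, g[3]], P[, g[4]])
      c1 <- c1 + mean(abs(gr$r1)) / 2
      c2 <- c2 + mean(abs(gr$r2)) / 2
      s1 <- sign(gr$r1); s2 <- sign(gr$r2)
      w <- 1 / (2 * n)
      gpen[, g[3]] <- gpen[, g[3]] + lambda1 * w * s1
      gpen[, g[4]] <- gpen[, g[4]] + lambda2 * w * s2
      gpen[, g[1]] <- gpen[, g[1]] - lambda1 * w * s1 * gr$d_f1_dE -
        lambda2 * w * s2 * gr$d_f2_dE
      gpen[, g[2]] <- gpen[, g[2]] - lambda1 * w * s1 * gr$d_f1_dnu -
        lambda2 * w * s2 * gr$d_f2_dnu
    }
    grad <- grad + sweep(gpen, 2, stats$y_sd, "*")
  }
  list(loss = mse + lambda1 * c1 + lambda2 * c2, grad = grad,
       terms = c(mse = mse, c1 = c1, c2 = c2))
}

# backprop through the MLP given dL/d(output); returns gradients
mlp_backward <- function(params, A, dout, activation) {
  L <- length(params$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dout
  for (l in L:1) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(params$W[[l]])) * act_grad(A[[l]], activation)
  }
  list(W = gW, b = gb)
}

#' Train the physics-informed material-property network
#'
#' Trains an MLP mapping the 16 normalised response features to the 10
#' normalised material-property targets with Adam, minimising the
#' normalised-MSE data term plus the physics penalties of [pinn_loss()]
#' evaluated on de-normalised predictions. Early stopping monitors the
#' validation loss and restores the best parameters. Training is
#' deterministic for a fixed `(dataset, config)`.
#'
#' @param ds A split [training_dataset] (see [split_and_normalize()]).
#' @param cfg A [net_config()].
#' @param init Optional parameter list to continue from (used by
#'   [fine_tune()]).
#' @param stats Optional normalisation statistics overriding the
#'   dataset's (used by [fine_tune()] so that an existing parameter set
#'   keeps its input/output scaling).
#' @return An object of class `pinn_net`: parameters, attached
#'   normalisation statistics, config, per-epoch loss curves and
#'   train/val/test accuracies.
#' @export
train_pinn <- function(ds, cfg = net_config(), init = NULL, stats = NULL) {
  stopifnot(inherits(ds, "training_dataset"), inherits(cfg, "net_config"))
  if (is.null(ds$splits) || is.null(ds$stats))
    stop("dataset must be split and normalised first (split_and_normalize)")
  st <- if (is.null(stats)) ds$stats else stats
  tr <- ds$splits$train
  Xn <- normalize_cols(ds$X, st$x_mean, st$x_sd)
  Yn <- normalize_cols(ds$Y, st$y_mean, st$y_sd)
  Xtr <- Xn[tr, , drop = FALSE]; Ytr <- Yn[tr, , drop = FALSE]
  Xval <- Xn[ds$splits$val, , drop = FALSE]
  Yval <- Yn[ds$splits$val, , drop = FALSE]

  params <- if (is.null(init))
    init_params(ncol(ds$X), cfg$hidden, ncol(ds$Y), cfg$seed) else init
  L <- length(params$W)
  adam <- list(mW = lapply(params$W, function(w) w * 0),
               vW = lapply(params$W, function(w) w * 0),
               mb = lapply(params$b, function(b) b * 0),
               vb = lapply(params$b, function(b) b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L

  n_tr <- nrow(Xtr)
  bs <- if (!is.finite(cfg$batch_size)) n_tr else min(cfg$batch_size, n_tr)
  set.seed(cfg$seed + 1L)
  curves <- list(total = numeric(0), mse = numeric(0),
                 c1 = numeric(0), c2 = numeric(0), val = numeric(0))
  best_val <- Inf; best_params <- params; since_best <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    idx <- if (bs < n_tr) sample.int(n_tr) else seq_len(n_tr)
    Xep <- if (cfg$input_noise > 0)
      Xtr + matrix(stats::rnorm(length(Xtr), sd = cfg$input_noise),
                   nrow = n_tr) else Xtr
    ep_terms <- c(mse = 0, c1 = 0, c2 = 0); ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n_tr, by = bs)) {
      rows <- idx[start:min(start + bs - 1L, n_tr)]
      A <- mlp_forward(params, Xep[rows, , drop = FALSE], cfg$activation)
      lg <- train_loss_grad(A[[L + 1L]], Ytr[rows, , drop = FALSE], st,
                            cfg$lambda1, cfg$lambda2)
      g <- mlp_backward(params, A, lg$grad, cfg$activation)
      t_step <- t_step + 1L
      corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
      for (l in seq_len(L)) {
        adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * g$W[[l]]
        adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * g$W[[l]]^2
        params$W[[l]] <- params$W[[l]] - cfg$lr * (adam$mW[[l]] / corr1) /
          (sqrt(adam$vW[[l]] / corr2) + eps)
        adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * g$b[[l]]
        adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * g$b[[l]]^2
        params$b[[l]] <- params$b[[l]] - cfg$lr * (adam$mb[[l]] / corr1) /
          (sqrt(adam$vb[[l]] / corr2) + eps)
      }
      ep_loss <- ep_loss + lg$loss; ep_terms <- ep_terms + lg$terms
      nb <- nb + 1L
    }
    if (!is.finite(ep_loss))
      stop("training diverged: non-finite loss at epoch ", epoch)
    curves$total <- c(curves$total, ep_loss / nb)
    curves$mse <- c(curves$mse, ep_terms[["mse"]] / nb)
    curves$c1 <- c(curves$c1, ep_terms[["c1"]] / nb)
    curves$c2 <- c(curves$c2, ep_terms[["c2"]] / nb)

    Aval <- mlp_forward(params, Xval, cfg$activation)
    vl <- train_loss_grad(Aval[[L + 1L]], Yval, st,
                          cfg$lambda1, cfg$lambda2)$loss
    curves$val <- c(curves$val, vl)
    if (vl < best_val - 1e-12) {
      best_val <- vl; best_params <- params; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience) break
    }
  }

  net <- structure(list(params = best_params, cfg = cfg, stats = st,
                        curves = curves, n_inputs = ncol(ds$X),
                        n_outputs = ncol(ds$Y), version = "1"),
                   class = "pinn_net")
  net$metrics <- evaluate_net(net, ds)
  net
}

# train/val/test accuracies of a net on a split dataset
evaluate_net <- function(net, ds) {
  sapply(ds$splits, function(idx) {
    pred <- predict(net, ds$X[idx, , drop = FALSE])
    accuracy(pred, ds$Y[idx, , drop = FALSE])
  })
}

#' Predict material properties from response features
#'
#' @param object A trained `pinn_net`.
#' @param newdata Numeric matrix (n x 16) or length-16 vector of response
#'   features in physical units.
#' @param ... Unused.
#' @return n x 10 matrix of predicted properties in natural column units.
#' @export
predict.pinn_net <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_inputs)
    stop("feature schema mismatch: expected ", object$n_inputs, " columns")
  Xn <- normalize_cols(newdata, object$stats$x_mean, object$stats$x_sd)
  A <- mlp_forward(object$params, Xn, object$cfg$activation)
  out <- denormalize_cols(A[[length(A)]], object$stats$y_mean,
                          object$stats$y_sd)
  colnames(out) <- target_names()
  out
}

#' @export
print.pinn_net <- function(x, ...) {
  cat(sprintf("pinn_net [%s], lambda = (%g, %g), %d epochs trained\n",
              paste(x$cfg$hidden, collapse = "-"), x$cfg$lambda1,
              x$cfg$lambda2, length(x$curves$total)))
  if (!is.null(x$metrics))
    cat(sprintf("  accuracy: train %.2f%%, val %.2f%%, test %.2f%%\n",
                x$metrics[["train"]], x$metrics[["val"]], x$metrics[["test"]]))
  invisible(x)
}

#' Sweep hidden-layer architectures
#'
#' Trains one network per architecture case and tabulates train,
#' validation and test accuracies. Cases are independent (each gets the
#' same seed and data), so the table does not depend on sweep order; a
#' failing case is recorded with `NA` accuracies and the sweep continues.
#'
#' @param ds A split [training_dataset].
#' @param cases List of hidden-layer integer vectors (default the 11-case
#'   sweep of [sweep_architectures()]) or of full [net_config()] objects.
#' @param base_cfg Template [net_config()] whose non-architecture fields
#'   are used for plain-vector cases.
#' @return Data frame with one row per case: architecture string, analysis
#'   count and the three accuracies. Trained nets are attached as the
#'   `"nets"` attribute.
#' @export
architecture_sweep <- function(ds, cases = sweep_architectures(),
                               base_cfg = net_config()) {
  stopifnot(length(cases) >= 1L)
  nets <- vector("list", length(cases))
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    cfg <- if (inherits(cs, "net_config")) cs else {
      cc <- base_cfg; cc$hidden <- as.integer(cs); cc
    }
    res <- tryCatch(train_pinn(ds, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(case = i,
                 architecture = paste0("[", paste(cfg$hidden, collapse = "-"), "]"),
                 n_analyses = nrow(ds$X), n_inputs = ncol(ds$X),
                 n_outputs = ncol(ds$Y), train_acc = NA_real_,
                 val_acc = NA_real_, test_acc = NA_real_,
                 error = conditionMessage(res))
    } else {
      nets[[i]] <<- res
      data.frame(case = i,
                 architecture = paste0("[", paste(cfg$hidden, collapse = "-"), "]"),
                 n_analyses = nrow(ds$X), n_inputs = ncol(ds$X),
                 n_outputs = ncol(ds$Y),
                 train_acc = res$metrics[["train"]],
                 val_acc = res$metrics[["val"]],
                 test_acc = res$metrics[["test"]], error = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "nets") <- nets
  out
}

#' Fine-tune a trained network on a calibration dataset
#'
#' Continues optimisation from the existing parameters on an enlarged or
#' calibration dataset, keeping the network's attached normalisation
#' statistics (so the parameters remain meaningful). Reports accuracies
#' before and after on the calibration splits.
#'
#' @param net A trained `pinn_net`.
#' @param calib_ds A split [training_dataset] with the same 16/10 schema.
#' @param epochs,lr Optional overrides of the training config.
#' @param ... Further `net_config` fields to override.
#' @return The fine-tuned `pinn_net`, with a `finetune` element recording
#'   before/after train/val/test accuracies.
#' @export
fine_tune <- function(net, calib_ds, epochs = NULL, lr = NULL, ...) {
  stopifnot(inherits(net, "pinn_net"), inherits(calib_ds, "training_dataset"))
  if (is.null(calib_ds$splits))
    stop("calibration dataset must be split first")
  if (ncol(calib_ds$X) != net$n_inputs || ncol(calib_ds$Y) != net$n_outputs)
    stop("schema mismatch between network and calibration dataset")
  cfg <- net$cfg
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
  if (!is.null(lr)) cfg$lr <- lr
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  before <- evaluate_net(net, calib_ds)
  out <- train_pinn(calib_ds, cfg, init = net$params, stats = net$stats)
  out$finetune <- list(before = before, after = out$metrics)
  out
}

#' Save / load a network checkpoint
#'
#' The checkpoint is self-describing: it carries the parameters, the
#' configuration, the normalisation statistics and a format version, and
#' round-trips to bit-identical predictions.
#'
#' @param net A `pinn_net`.
#' @param path Checkpoint file path.
#' @return `path` invisibly; `read_checkpoint()` returns the `pinn_net`.
#' @export
write_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "pinn_net"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "pinn_net")) stop("not a pinn_net checkpoint")
  net
}
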