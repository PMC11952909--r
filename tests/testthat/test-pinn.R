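test_that("physics-informed loss vanishes for consistent perfect prediction", {
  y <- consistent_sample()
  l <- pinn_loss(y, y, lambda1 = 1, lambda2 = 1)
  expect_equal(as.numeric(l), 0, tolerance = 1e-15)
  expect_identical(attr(l, "n_clamped"), 0L)
})

test_that("with zero penalty weights the loss reduces to plain MSE", {
  set.seed(1)
  pred <- matrix(runif(50, 1, 5), 5, 10)
  target <- matrix(runif(50, 1, 5), 5, 10)
  l <- pinn_loss(pred, target, lambda1 = 0, lambda2 = 0)
  expect_equal(as.numeric(l), mean((pred - target)^2), tolerance = 1e-14)
})

test_that("loss on a crafted sample matches manual arithmetic", {
  # E = 2, nu = 0.25: consistent k = 2/(3*0.5) = 4/3, mu = 2/2.5 = 0.8.
  # Prediction equals the (consistent) target except bone k is off by
  # +0.1. With lambda1 = 1, lambda2 = 0:
  #   mse = 0.1^2 / 10 = 0.001
  #   c1  = (|0.1| + 0) / 2 = 0.05  (bone and disc groups averaged)
  #   total = 0.001 + 1 * 0.05 = 0.051
  target <- consistent_sample(E_b = 2, nu_b = 0.25)
  pred <- target
  pred[["k_bone_GPa"]] <- pred[["k_bone_GPa"]] + 0.1
  l <- pinn_loss(pred, target, lambda1 = 1, lambda2 = 0)
  expect_equal(as.numeric(l), 0.051, tolerance = 1e-12)
  expect_equal(attr(l, "mse"), 0.001, tolerance = 1e-12)
  expect_equal(attr(l, "c1"), 0.05, tolerance = 1e-12)
  expect_identical(attr(l, "c2"), 0)
  # bookkeeping identity: total = mse + lambda1 c1 + lambda2 c2
  l2 <- pinn_loss(pred, target, lambda1 = 0.3, lambda2 = 0.7)
  expect_equal(as.numeric(l2),
               attr(l2, "mse") + 0.3 * attr(l2, "c1") + 0.7 * attr(l2, "c2"),
               tolerance = 1e-14)
})

test_that("predicted nu at the incompressible limit is clamped, not fatal", {
  target <- consistent_sample()
  pred <- target
  pred[["nu_bone"]] <- 0.62
  l <- pinn_loss(pred, target, lambda1 = 1, lambda2 = 1)
  expect_true(is.finite(as.numeric(l)))
  expect_identical(attr(l, "n_clamped"), 1L)
})

test_that("accuracy metric has its closed-form values", {
  y <- matrix(runif(40, 1, 10), 4, 10)
  expect_identical(accuracy(y, y), 100)
  expect_equal(accuracy(1.1 * y, y), 90, tolerance = 1e-10)
  # independent element-by-element loop
  pred <- y * matrix(runif(40, 0.5, 1.5), 4, 10)
  acc_loop <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y)))
    acc_loop <- acc_loop + max(0, 1 - abs(pred[i, j] - y[i, j]) / y[i, j])
  expect_equal(accuracy(pred, y), 100 * acc_loop / length(y),
               tolerance = 1e-12)
})

test_that("the network can overfit a tiny training set", {
  ds <- fix_toy_dataset(n = 10, seed = 2)
  ds$splits <- list(train = 1:10, val = 1:10, test = 1:10)
  ds <- local({
    d <- ds
    d$stats <- list(x_mean = colMeans(d$X), x_sd = apply(d$X, 2, sd),
                    y_mean = colMeans(d$Y), y_sd = apply(d$Y, 2, sd))
    d
  })
  net <- train_pinn(ds, net_config(hidden = c(64, 32), epochs = 4000,
                                   input_noise = 0, patience = Inf,
                                   seed = 3))
  expect_gt(net$metrics[["train"]], 99)
})

test_that("training is deterministic and records the loss decomposition", {
  ds <- fix_toy_dataset(n = 20, seed = 4)
  ds <- split_and_normalize(ds, seed = 1)
  cfg <- net_config(hidden = c(8), epochs = 50, seed = 5)
  n1 <- train_pinn(ds, cfg)
  n2 <- train_pinn(ds, cfg)
  expect_identical(n1$params, n2$params)
  expect_equal(n1$curves$total,
               n1$curves$mse + cfg$lambda1 * n1$curves$c1 +
                 cfg$lambda2 * n1$curves$c2, tolerance = 1e-12)
})

test_that("checkpoints round-trip to identical predictions", {
  ds <- fix_toy_dataset(n = 20, seed = 4)
  ds <- split_and_normalize(ds, seed = 1)
  net <- train_pinn(ds, net_config(hidden = c(8), epochs = 30, seed = 5))
  path <- withr::local_tempfile(fileext = ".ckpt")
  write_checkpoint(net, path)
  back <- read_checkpoint(path)
  expect_identical(predict(back, ds$X), predict(net, ds$X))
  expect_error(suppressWarnings(
    read_checkpoint(withr::local_tempfile(fileext = ".bad"))))
})

test_that("architecture sweep rows are independent of sweep order", {
  ds <- fix_toy_dataset(n = 30, seed = 6)
  ds <- split_and_normalize(ds, seed = 1)
  cfg <- net_config(epochs = 40, seed = 2)
  cases <- list(c(8L), c(16L, 8L))
  fwd <- architecture_sweep(ds, cases, base_cfg = cfg)
  rev_ <- architecture_sweep(ds, rev(cases), base_cfg = cfg)
  expect_identical(nrow(fwd), 2L)
  expect_equal(fwd$train_acc, rev(rev_$train_acc), tolerance = 1e-12)
  # single-case sweep equals a direct training run
  single <- architecture_sweep(ds, list(c(8L)), base_cfg = cfg)
  direct <- train_pinn(ds, local({ c <- cfg; c$hidden <- 8L; c }))
  expect_equal(single$train_acc, direct$metrics[["train"]], tolerance = 1e-12)
  expect_equal(single$test_acc, direct$metrics[["test"]], tolerance = 1e-12)
})

test_that("fine-tuning with zero learning rate changes nothing", {
  ds <- fix_toy_dataset(n = 20, seed = 8)
  ds <- split_and_normalize(ds, seed = 1)
  net <- train_pinn(ds, net_config(hidden = c(8), epochs = 30, seed = 5))
  ft <- fine_tune(net, ds, epochs = 10, lr = 0, patience = Inf)
  expect_equal(ft$metrics, net$metrics, tolerance = 1e-9)
  expect_equal(ft$finetune$before, ft$finetune$after, tolerance = 1e-9)
})

test_that("fine-tuning rejects schema mismatches", {
  ds <- fix_toy_dataset(n = 20, seed = 8)
  ds <- split_and_normalize(ds, seed = 1)
  net <- train_pinn(ds, net_config(hidden = c(8), epochs = 10, seed = 5))
  bad <- ds
  bad$X <- bad$X[, 1:12]
  expect_error(fine_tune(net, bad), "schema")
  expect_error(predict(net, ds$X[, 1:12]), "schema")
})
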