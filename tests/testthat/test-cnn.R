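tiny_config <- function(seed = 1L) {
  cnn_config(conv_filters = c(3, 4), kernel_sizes = c(5, 3),
             pool_sizes = c(2, 2), mlp_widths = c(8, 1),
             window_len = 24, input_channels = 2, batch_size = 8,
             seed = seed)
}

test_that("shape propagation through the convolution/pooling chain", {
  shp <- cnn_shapes(cnn_config())
  expect_equal(shp$conv_out, c(276, 38, 4))
  expect_equal(shp$pool_out, c(46, 9, 2))
  expect_equal(shp$flat, 256)
  expect_error(cnn_config(window_len = 20),
               class = "hybridgait_config_error")
})

test_that("model building is deterministic in the seed", {
  m1 <- build_model(tiny_config())
  m2 <- build_model(tiny_config())
  expect_equal(m1$layers, m2$layers)
  m3 <- build_model(tiny_config(seed = 2L))
  expect_false(isTRUE(all.equal(m1$layers[[1]]$W, m3$layers[[1]]$W)))
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- tiny_config()
  model <- build_model(cfg)
  set.seed(3)
  n <- 4
  X <- array(rnorm(n * cfg$window_len * 2), dim = c(n, cfg$window_len, 2))
  y <- rnorm(n)
  loss_of <- function(m) {
    fw <- hybridgait:::cnn_forward_raw(m, X)
    mean((fw$yhat - y)^2)
  }
  fw <- hybridgait:::cnn_forward_raw(model, X, keep = TRUE)
  grads <- hybridgait:::cnn_backward(model, X, fw$caches,
                                     2 * (fw$yhat - y) / n)
  eps <- 1e-5
  for (li in c(1, 2, 3, 4)) {
    # probe a few weights per layer
    set.seed(li)
    probe <- sample(length(model$layers[[li]]$W), 5)
    for (p in probe) {
      mp <- model; mp$layers[[li]]$W[p] <- mp$layers[[li]]$W[p] + eps
      mm <- model; mm$layers[[li]]$W[p] <- mm$layers[[li]]$W[p] - eps
      g_num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(grads[[li]]$W[p], g_num, tolerance = 1e-4)
    }
  }
})

test_that("training a tiny model reduces the training loss", {
  set.seed(11)
  n <- 120
  L <- 24
  X <- array(abs(rnorm(n * L * 2)), dim = c(n, L, 2))
  y <- 10 * (sqrt(apply(X[, , 2]^2, 1, mean)) -
               sqrt(apply(X[, , 1]^2, 1, mean)))
  ds <- structure(list(windows = X, torques = y,
                       split = list(train = 1:72, val = 73:96,
                                    test = 97:120)),
                  class = "emg_torque_dataset")
  tr <- train(build_model(tiny_config()), ds, max_epochs = 15, patience = 15)
  expect_lt(tail(tr$log$train_loss, 1), tr$log$train_loss[1])
  expect_true(is.finite(tr$metrics$rmse))
  # overlapping splits are rejected
  ds_bad <- ds; ds_bad$split$val <- 1:24
  expect_error(train(build_model(tiny_config()), ds_bad))
})

test_that("save/load round-trips predictions exactly", {
  cnn <- get_trained_cnn()
  f <- tempfile(fileext = ".rds")
  save_cnn(cnn$model, f)
  m2 <- load_cnn(f)
  ds <- cnn$dataset
  idx <- ds$split$test[1:20]
  X <- ds$windows[idx, , , drop = FALSE]
  expect_equal(estimate_torque(m2, X), estimate_torque(cnn$model, X),
               tolerance = 1e-12)
  unlink(f)
})

test_that("estimate_torque validates window shape and bounds output", {
  cnn <- get_trained_cnn()
  L <- cnn$model$config$window_len
  expect_error(estimate_torque(cnn$model, matrix(0, L - 1, 2)),
               class = "hybridgait_shape_error")
  expect_error(estimate_torque(cnn$model, matrix(0, L, 3)),
               class = "hybridgait_shape_error")
  tau <- estimate_torque(cnn$model, matrix(0.2, L, 2))
  expect_lte(abs(tau), cnn$model$config$tau_bound)
})

test_that("peak accuracy measures absolute peak agreement", {
  expect_equal(peak_accuracy(c(0, 5, -2), c(0, 5, -2)), 100)
  expect_equal(peak_accuracy(c(0, 2.5), c(0, 5)), 50)
  expect_equal(peak_accuracy(c(0, 20), c(0, 5)), 0)  # clamped
  expect_error(peak_accuracy(c(0, 1), c(0, 0)),
               class = "hybridgait_domain_error")
})

test_that("a trailing-RMS linear oracle recovers the noise-free mapping", {
  ds0 <- gen_isometric_dataset(n_samples = 150, noise_sigma = 0, seed = 21)
  L <- dim(ds0$windows)[2]
  tail_cols <- (L - ds0$torque_window + 1):L
  feat <- sqrt(rowMeans(ds0$windows[, tail_cols, 2]^2)) -
    sqrt(rowMeans(ds0$windows[, tail_cols, 1]^2))
  fit <- stats::lm(ds0$torques ~ feat)
  expect_lt(sqrt(mean(stats::residuals(fit)^2)), 0.1)

  # permutation control: shuffled labels leave no recoverable structure
  set.seed(1)
  y_perm <- sample(ds0$torques)
  fit_p <- stats::lm(y_perm ~ feat)
  expect_gt(sqrt(mean(stats::residuals(fit_p)^2)),
            0.5 * stats::sd(ds0$torques))
})
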