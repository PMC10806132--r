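# One-dimensional convolutional network mapping two-channel EMG envelope
# windows to ankle joint torque.
#
# Architecture: three convolution layers (128 filters each, kernels 13/9/6,
# stride 1, ReLU), each followed by an average-pooling layer (sizes 6/4/2),
# a flatten layer, then a five-layer MLP (widths 129/128/128/64/1) with ReLU
# activations and a final Tanh. The bounded Tanh output is rescaled to the
# torque range by a fixed affine constant `tau_max`. Trained with Adam on a
# mean-squared-error loss with early stopping on the validation loss.
#
# Implemented directly on BLAS matrix products (im2col/col2im); no external
# deep-learning runtime is used.

#' CNN configuration
#'
#' @param conv_filters filters per convolution layer.
#' @param kernel_sizes kernel length per convolution layer.
#' @param pool_sizes average-pooling length per convolution layer.
#' @param mlp_widths widths of the dense head; the last must be 1.
#' @param window_len input window length, samples.
#' @param input_channels number of EMG channels.
#' @param tau_max affine output scale, Nm: predictions span
#'   `[-tau_max, tau_max]`.
#' @param tau_bound physiological sanity bound on `|tau|`, Nm.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return an object of class `cnn_config`.
#' @export
cnn_config <- function(conv_filters = c(128, 128, 128),
                       kernel_sizes = c(13, 9, 6),
                       pool_sizes = c(6, 4, 2),
                       mlp_widths = c(129, 128, 128, 64, 1),
                       window_len = 288,
                       input_channels = 2,
                       tau_max = 60,
                       tau_bound = 150,
                       lr = 1e-3,
                       batch_size = 64,
                       seed = 1L) {
  stopifnot(length(conv_filters) == length(kernel_sizes),
            length(conv_filters) == length(pool_sizes),
            all(conv_filters > 0), all(kernel_sizes > 0), all(pool_sizes > 0),
            all(mlp_widths > 0),
            mlp_widths[length(mlp_widths)] == 1,
            window_len > 0, input_channels > 0, tau_max > 0, lr > 0)
  cfg <- structure(
    list(conv_filters = as.integer(conv_filters),
         kernel_sizes = as.integer(kernel_sizes),
         pool_sizes = as.integer(pool_sizes),
         mlp_widths = as.integer(mlp_widths),
         window_len = as.integer(window_len),
         input_channels = as.integer(input_channels),
         tau_max = tau_max, tau_bound = tau_bound,
         lr = lr, batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "cnn_config")
  cnn_shapes(cfg)  # validates the pooling chain
  cfg
}

#' Layer output lengths of the convolution/pooling chain
#'
#' @param config a [cnn_config()].
#' @return list with per-stage lengths `conv_out`, `pool_out` and the
#'   flatten length `flat`.
#' @export
cnn_shapes <- function(config) {
  L <- config$window_len
  conv_out <- integer(0); pool_out <- integer(0)
  for (i in seq_along(config$conv_filters)) {
    L <- L - config$kernel_sizes[i] + 1L
    if (L < 1L) {
      abort("window_len too short for the convolution chain",
            "hybridgait_config_error")
    }
    conv_out <- c(conv_out, L)
    L <- L %/% config$pool_sizes[i]
    if (L < 1L) {
      abort("window_len too short for the pooling chain",
            "hybridgait_config_error")
    }
    pool_out <- c(pool_out, L)
  }
  list(conv_out = conv_out, pool_out = pool_out,
       flat = L * config$conv_filters[length(config$conv_filters)])
}

#' Build a CNN model with seeded initialization
#'
#' He initialization for ReLU layers, Xavier for the Tanh output layer.
#' Two builds with the same config (and seed) produce identical parameters.
#'
#' @param config a [cnn_config()].
#' @return an object of class `cnn_model`.
#' @export
build_model <- function(config) {
  shp <- cnn_shapes(config)
  rng <- local({
    set.seed(config$seed)
    NULL
  })
  layers <- list()
  cin <- config$input_channels
  for (i in seq_along(config$conv_filters)) {
    k <- config$kernel_sizes[i]; f <- config$conv_filters[i]
    fan_in <- k * cin
    layers[[length(layers) + 1L]] <- list(
      type = "conv", k = k, filters = f, pool = config$pool_sizes[i],
      W = matrix(stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f),
      b = numeric(f))
    cin <- f
  }
  din <- shp$flat
  nw <- length(config$mlp_widths)
  for (i in seq_len(nw)) {
    dout <- config$mlp_widths[i]
    sd <- if (i == nw) sqrt(1 / din) else sqrt(2 / din)
    layers[[length(layers) + 1L]] <- list(
      type = "dense", activation = if (i == nw) "tanh" else "relu",
      W = matrix(stats::rnorm(din * dout, sd = sd), din, dout),
      b = numeric(dout))
    din <- dout
  }
  structure(list(config = config, shapes = shp, layers = layers,
                 norm = NULL, cache = new.env(parent = emptyenv())),
            class = "cnn_model")
}

# im2col gather-index matrix for a conv layer: rows (sample, out-position),
# columns (channel, kernel-offset); cached per (layer length, channels,
# kernel, batch size).
im2col_index <- function(model, L, C, k, n) {
  key <- paste(L, C, k, n, sep = "_")
  idx <- model$cache[[key]]
  if (is.null(idx)) {
    Lo <- L - k + 1L
    # flat index of (i, t, c) in an (n, L, C) array: i + (t-1) n + (c-1) n L
    i <- rep(seq_len(n), times = Lo)
    p <- rep(seq_len(Lo), each = n)
    base <- i + (p - 1L) * n
    idx <- matrix(0L, nrow = n * Lo, ncol = k * C)
    col <- 0L
    for (c in seq_len(C)) {
      off_c <- (c - 1L) * n * L
      for (j in seq_len(k)) {
        col <- col + 1L
        idx[, col] <- base + (j - 1L) * n + off_c
      }
    }
    model$cache[[key]] <- idx
  }
  idx
}

# Forward pass. X: array (n, window_len, channels), already normalized.
# Returns predictions and, when `keep = TRUE`, the per-layer caches needed
# for backpropagation.
cnn_forward_raw <- function(model, X, keep = FALSE) {
  n <- dim(X)[1]
  A <- X
  caches <- if (keep) vector("list", length(model$layers)) else NULL
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    if (layer$type == "conv") {
      L <- dim(A)[2]; C <- dim(A)[3]
      k <- layer$k; Lo <- L - k + 1L; f <- layer$filters
      M <- A[im2col_index(model, L, C, k, n)]
      dim(M) <- c(n * Lo, k * C)
      Z <- M %*% layer$W
      Z <- sweep(Z, 2L, layer$b, "+")
      mask <- Z > 0
      Z[!mask] <- 0
      # average pooling
      s <- layer$pool; Lp <- Lo %/% s
      dim(Z) <- c(n, Lo, f)
      Zc <- Z[, seq_len(s * Lp), , drop = FALSE]
      dim(Zc) <- c(n, s, Lp, f)
      P <- aperm(Zc, c(2, 1, 3, 4))
      dim(P) <- c(s, n * Lp * f)
      Y <- .colMeans(P, s, n * Lp * f)
      dim(Y) <- c(n, Lp, f)
      if (keep) {
        caches[[li]] <- list(M = M, mask = mask, L = L, C = C, Lo = Lo,
                             Lp = Lp, f = f, s = s)
      }
      A <- Y
    } else {
      if (!is.matrix(A)) A <- matrix(A, n)  # flatten (n, L, F) -> n x (L F)
      Z <- A %*% layer$W
      Z <- sweep(Z, 2L, layer$b, "+")
      if (layer$activation == "relu") {
        mask <- Z > 0
        Z[!mask] <- 0
        if (keep) caches[[li]] <- list(A = A, mask = mask)
      } else {
        Z <- tanh(Z)
        if (keep) caches[[li]] <- list(A = A, tanh = Z)
      }
      A <- Z
    }
  }
  list(yhat = model$config$tau_max * as.numeric(A), caches = caches)
}

# Backward pass; returns gradients in the same structure as model$layers.
cnn_backward <- function(model, X, caches, dyhat) {
  n <- dim(X)[1]
  grads <- vector("list", length(model$layers))
  # output scale; the tanh derivative is applied at the last dense layer
  dZ <- matrix(dyhat * model$config$tau_max, ncol = 1)
  for (li in rev(seq_along(model$layers))) {
    layer <- model$layers[[li]]
    cc <- caches[[li]]
    if (layer$type == "dense") {
      if (layer$activation == "tanh") {
        dZ <- dZ * (1 - cc$tanh^2)
      } else {
        dZ <- dZ * cc$mask
      }
      grads[[li]] <- list(W = crossprod(cc$A, dZ), b = colSums(dZ))
      dZ <- dZ %*% t(layer$W)
    } else {
      # dZ arrives as n x (Lp f) (flattened) or (n, Lp, f)
      s <- cc$s; Lp <- cc$Lp; f <- cc$f; Lo <- cc$Lo
      dY <- dZ / s
      dim(dY) <- c(n, Lp, f)
      # un-pool: broadcast to the s pooled positions
      dP <- array(0, dim = c(n, Lo, f))
      v <- as.vector(dY)
      dE <- array(rep(v, each = s), dim = c(s, n, Lp, f))
      dE <- aperm(dE, c(2, 1, 3, 4))
      dim(dE) <- c(n, s * Lp, f)
      dP[, seq_len(s * Lp), ] <- dE
      dim(dP) <- c(n * Lo, f)
      dP[!cc$mask] <- 0
      grads[[li]] <- list(W = crossprod(cc$M, dP), b = colSums(dP))
      if (li > 1L) {
        dM <- dP %*% t(layer$W)
        k <- layer$k; C <- cc$C; L <- cc$L
        dA <- array(0, dim = c(n, L, C))
        col <- 0L
        for (c in seq_len(C)) {
          for (j in seq_len(k)) {
            col <- col + 1L
            dA[, j:(j + Lo - 1L), c] <- dA[, j:(j + Lo - 1L), c] +
              matrix(dM[, col], n, Lo)
          }
        }
        dZ <- dA
      }
    }
  }
  grads
}

# Per-channel z-score normalization using stored (training-split) statistics.
cnn_normalize <- function(model, X) {
  nm <- model$norm
  if (is.null(nm)) return(X)
  for (c in seq_len(dim(X)[3])) {
    X[, , c] <- (X[, , c] - nm$mean[c]) / nm$sd[c]
  }
  X
}

# Chunked prediction on raw (unnormalized) windows.
cnn_predict <- function(model, X, chunk = 256L) {
  n <- dim(X)[1]
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    Xb <- cnn_normalize(model, X[i:j, , , drop = FALSE])
    out[i:j] <- cnn_forward_raw(model, Xb)$yhat
    i <- j + 1L
  }
  out
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(model, state, grads, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (li in seq_along(model$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    st <- state[[li]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    model$layers[[li]]$W <- model$layers[[li]]$W -
      lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    model$layers[[li]]$b <- model$layers[[li]]$b -
      lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[li]] <- st
  }
  list(model = model, state = state)
}

#' Train the CNN torque regressor
#'
#' Minimizes mean-squared error with Adam; stops early when the validation
#' loss has not improved for `patience` epochs and restores the best
#' validation weights. Per-channel z-score normalization statistics are
#' computed on the training split and stored in the model.
#'
#' @param model a [build_model()] result.
#' @param dataset an `emg_torque_dataset` (see [gen_isometric_dataset()]):
#'   list with `windows` (array n x window_len x channels), `torques` (Nm,
#'   plantar flexion positive) and `split` (index vectors `train`, `val`,
#'   `test`).
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience, epochs.
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained), `metrics` (list: `rmse` Nm and
#'   `peak_accuracy` % on the test split) and `log` (data frame of per-epoch
#'   training and validation losses).
#' @export
train <- function(model, dataset, max_epochs = 60L, patience = 10L,
                  verbose = FALSE) {
  sp <- dataset$split
  stopifnot(length(sp$train) > 0, length(sp$val) > 0, length(sp$test) > 0,
            length(intersect(sp$train, sp$val)) == 0,
            length(intersect(sp$train, sp$test)) == 0)
  cfg <- model$config
  Xtr <- dataset$windows[sp$train, , , drop = FALSE]
  ytr <- dataset$torques[sp$train]
  mu <- apply(Xtr, 3, mean)
  sdv <- apply(Xtr, 3, stats::sd)
  sdv[sdv < 1e-12] <- 1
  model$norm <- list(mean = mu, sd = sdv)
  Xtr <- cnn_normalize(model, Xtr)
  Xval <- cnn_normalize(model, dataset$windows[sp$val, , , drop = FALSE])
  yval <- dataset$torques[sp$val]

  ntr <- dim(Xtr)[1]
  bs <- cfg$batch_size
  state <- adam_init(model$layers)
  set.seed(cfg$seed + 1L)
  best_val <- Inf; best_layers <- model$layers; wait <- 0L; step <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(ntr)
    tr_loss <- 0; nb <- 0L
    for (start in seq(1L, ntr, by = bs)) {
      ix <- ord[start:min(start + bs - 1L, ntr)]
      Xb <- Xtr[ix, , , drop = FALSE]
      yb <- ytr[ix]
      fw <- cnn_forward_raw(model, Xb, keep = TRUE)
      err <- fw$yhat - yb
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        abort("training diverged: non-finite loss", "hybridgait_divergence_error")
      }
      grads <- cnn_backward(model, Xb, fw$caches, 2 * err / length(err))
      step <- step + 1L
      up <- adam_step(model, state, grads, step, cfg$lr)
      model <- up$model; state <- up$state
      tr_loss <- tr_loss + loss; nb <- nb + 1L
    }
    val_pred <- {
      # model already holds norm; Xval is normalized, use raw forward
      n <- dim(Xval)[1]; out <- numeric(n); i <- 1L
      while (i <= n) {
        j <- min(i + 255L, n)
        out[i:j] <- cnn_forward_raw(model, Xval[i:j, , , drop = FALSE])$yhat
        i <- j + 1L
      }
      out
    }
    val_loss <- mean((val_pred - yval)^2)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss / nb,
                                 val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      tr_loss / nb, val_loss))
    }
    if (val_loss < best_val - 1e-8) {
      best_val <- val_loss
      best_layers <- model$layers
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model$layers <- best_layers
  ytest <- dataset$torques[sp$test]
  test_pred <- cnn_predict(model, dataset$windows[sp$test, , , drop = FALSE])
  metrics <- list(
    rmse = sqrt(mean((test_pred - ytest)^2)),
    peak_accuracy = if (max(abs(ytest)) > 0) {
      peak_accuracy(test_pred, ytest)
    } else NA_real_
  )
  list(model = model, metrics = metrics, log = log)
}

#' Estimate ankle torque from a two-channel EMG envelope window
#'
#' @param model a trained [build_model()] result (the `model` element of
#'   [train()]'s return value).
#' @param window numeric matrix `window_len x channels` (or array
#'   `n x window_len x channels` for a batch).
#' @return torque estimate(s), Nm, plantar flexion positive; clipped to the
#'   configured physiological bound.
#' @export
estimate_torque <- function(model, window) {
  cfg <- model$config
  if (is.matrix(window)) {
    dim(window) <- c(1L, nrow(window), ncol(window))
  }
  if (dim(window)[2] != cfg$window_len ||
      dim(window)[3] != cfg$input_channels) {
    abort(sprintf("window shape %d x %d does not match config %d x %d",
                  dim(window)[2], dim(window)[3],
                  cfg$window_len, cfg$input_channels),
          "hybridgait_shape_error")
  }
  clamp(cnn_predict(model, window), -cfg$tau_bound, cfg$tau_bound)
}

#' Peak accuracy of a torque prediction
#'
#' `100 * (1 - | max|pred| - max|true| | / max|true|)`, clamped to
#' `[0, 100]`: agreement of the absolute peak magnitudes of the two series.
#'
#' @param predicted,true aligned torque series, Nm.
#' @return peak accuracy in percent.
#' @export
peak_accuracy <- function(predicted, true) {
  stopifnot(length(predicted) == length(true))
  pt <- max(abs(true))
  if (pt == 0) {
    abort("peak accuracy undefined: true series is all zero",
          "hybridgait_domain_error")
  }
  clamp(100 * (1 - abs(max(abs(predicted)) - pt) / pt), 0, 100)
}

#' Save/load a trained CNN model
#'
#' Single-file checkpoint containing the layer weights, normalization
#' statistics and the full configuration.
#'
#' @param model a `cnn_model`.
#' @param path file path.
#' @return `load_cnn()` returns the model; `save_cnn()` returns `path`
#'   invisibly.
#' @export
save_cnn <- function(model, path) {
  saveRDS(list(config = unclass(model$config), norm = model$norm,
               layers = model$layers), path)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  d <- readRDS(path)
  cfg <- do.call(cnn_config, d$config[setdiff(names(d$config), character(0))])
  m <- build_model(cfg)
  m$layers <- d$layers
  m$norm <- d$norm
  m
}
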