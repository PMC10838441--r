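#' Configuration of the spectral attention CNN
#'
#' Collects the architecture and optimization settings of the 1-D
#' convolutional regression network. The fixed skeleton is: spectral
#' attention gate (squeeze-and-excitation over bands) -> stem convolution
#' (stride 2) -> average pooling (stride 3), so the stem emits a feature map
#' of exactly 1/6 the input length -> Inception block (parallel kernels 1,
#' 3, 5 plus an average-pooling branch, concatenated) -> two fully
#' connected layers with a ReLU between them -> scalar SPAD estimate.
#'
#' @param n_bands input spectrum length; must be divisible by 6 and by
#'   `se_reduction` (default 180).
#' @param se_reduction bottleneck ratio of the attention gate (default 4).
#' @param stem_channels channels of the stem convolution (default 16).
#' @param stem_kernel stem kernel width (default 7).
#' @param inception_channels channels per Inception branch (default 16;
#'   four branches concatenate to 4x this).
#' @param fc_hidden width of the first fully connected layer (default 64).
#' @param learning_rate peak Adam learning rate (default 1e-4).
#' @param lr_min floor of the cosine learning-rate schedule (default 0).
#' @param batch_size minibatch size (default 6).
#' @param epochs training epochs (default 500).
#' @param lr_restart cosine-annealing restart period in epochs (default 200).
#' @param l2 coefficient of the L2 penalty on weights (default 1e-4).
#' @param attention `FALSE` ablates the gate to the identity, giving the
#'   plain 1-D Inception comparator.
#' @param augment apply offset/slope jitter to training batches.
#' @param augment_cfg an [augmentation_config()].
#' @param standardize_y centre/scale the response during optimization
#'   (predictions are always returned in SPAD units).
#' @param seed integer seed for initialization, shuffling and augmentation.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(n_bands = 180, se_reduction = 4, stem_channels = 16,
                         stem_kernel = 7, inception_channels = 16,
                         fc_hidden = 64, learning_rate = 1e-4, lr_min = 0,
                         batch_size = 6, epochs = 500, lr_restart = 200,
                         l2 = 1e-4, attention = TRUE, augment = TRUE,
                         augment_cfg = augmentation_config(),
                         standardize_y = TRUE, seed = 1) {
  if (n_bands %% 6 != 0)
    stop("'n_bands' must be divisible by 6 (stem downsamples by exactly 1/6)")
  if (n_bands %% se_reduction != 0)
    stop("'n_bands' must be divisible by 'se_reduction'")
  if (stem_kernel < 2) stop("'stem_kernel' must be at least 2")
  if (epochs < 1) stop("'epochs' must be at least 1")
  if (lr_restart < 1) stop("'lr_restart' must be at least 1")
  if (batch_size < 1) stop("'batch_size' must be at least 1")
  structure(list(n_bands = as.integer(n_bands),
                 se_reduction = as.integer(se_reduction),
                 stem_channels = as.integer(stem_channels),
                 stem_kernel = as.integer(stem_kernel),
                 inception_channels = as.integer(inception_channels),
                 fc_hidden = as.integer(fc_hidden),
                 learning_rate = learning_rate, lr_min = lr_min,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_restart = as.integer(lr_restart), l2 = l2,
                 attention = isTRUE(attention), augment = isTRUE(augment),
                 augment_cfg = augment_cfg,
                 standardize_y = isTRUE(standardize_y),
                 seed = as.integer(seed)),
            class = "model_config")
}

# He-normal weight matrix; fan-in is the row count
he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / nrow)), nrow, ncol)
}

#' Build the spectral attention CNN
#'
#' Allocates and deterministically initializes all parameters (He-normal
#' weights, zero biases) under `cfg$seed`.
#'
#' @param cfg a [model_config()].
#' @return An object of class `"spad_cnn"`.
#' @export
build_model <- function(cfg = model_config()) {
  if (!inherits(cfg, "model_config")) stop("'cfg' must be a model_config")
  n <- cfg$n_bands
  C <- cfg$stem_channels
  C2 <- cfg$inception_channels
  L_inc <- n %/% 6L
  flat <- 4L * C2 * L_inc
  params <- with_seed(cfg$seed, {
    p <- list()
    if (cfg$attention) {
      h <- n %/% cfg$se_reduction
      p$se_W1 <- he_init(n, h); p$se_b1 <- numeric(h)
      p$se_W2 <- he_init(h, n); p$se_b2 <- numeric(n)
    }
    p$stem_W <- he_init(cfg$stem_kernel, C); p$stem_b <- numeric(C)
    p$inc1_W <- he_init(C, C2);      p$inc1_b <- numeric(C2)
    p$inc3_W <- he_init(3L * C, C2); p$inc3_b <- numeric(C2)
    p$inc5_W <- he_init(5L * C, C2); p$inc5_b <- numeric(C2)
    p$incp_W <- he_init(C, C2);      p$incp_b <- numeric(C2)
    p$fc1_W <- he_init(flat, cfg$fc_hidden); p$fc1_b <- numeric(cfg$fc_hidden)
    p$fc2_W <- he_init(cfg$fc_hidden, 1L);   p$fc2_b <- numeric(1L)
    p
  })
  pad_total <- cfg$stem_kernel - 2L
  structure(list(params = params, cfg = cfg,
                 dims = list(stem_len = n %/% 2L, pooled_len = L_inc,
                             flat = flat,
                             stem_pl = pad_total %/% 2L,
                             stem_pr = pad_total - pad_total %/% 2L),
                 y_center = 0, y_scale = 1, trained = FALSE),
            class = "spad_cnn")
}

#' @export
print.spad_cnn <- function(x, ...) {
  cat(sprintf(
    "<spad_cnn> %d bands -> stem %d -> inception %d x %d -> fc %d -> 1 (%s attention, %s, %d parameters)\n",
    x$cfg$n_bands, x$dims$stem_len, 4L * x$cfg$inception_channels,
    x$dims$pooled_len, x$cfg$fc_hidden,
    if (x$cfg$attention) "with" else "without",
    if (x$trained) "trained" else "untrained", count_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model a [build_model()] result.
#' @return Integer parameter count (a pure function of the configuration).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Squeeze-and-excitation recalibration of a spectrum
#'
#' The attention gate of the network: each band (treated as a channel whose
#' global-average-pooled descriptor is the band value itself) is passed
#' through a bottleneck of two fully connected layers with a ReLU between
#' them, then a sigmoid produces a per-band weight in (0, 1) that rescales
#' the input.
#'
#' @param x spectrum vector of length `n_bands`, or a `batch x n_bands`
#'   matrix.
#' @param params attention parameters: a list with `se_W1`, `se_b1`,
#'   `se_W2`, `se_b2` (e.g. `model$params`), or a `"spad_cnn"` model.
#' @return List with `output` (recalibrated spectrum, same shape as `x`)
#'   and `weights` (the sigmoid gate values).
#' @export
se_recalibrate <- function(x, params) {
  if (inherits(params, "spad_cnn")) params <- params$params
  if (is.null(params$se_W1)) stop("no attention parameters present")
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, nrow = 1L) else x
  if (ncol(X) != nrow(params$se_W1))
    stop(sprintf("spectrum length %d does not match attention input size %d",
                 ncol(X), nrow(params$se_W1)))
  H <- relu(fc_forward(X, params$se_W1, params$se_b1))
  w <- sigmoid(fc_forward(H, params$se_W2, params$se_b2))
  out <- w * X
  if (vec) list(output = drop(out), weights = drop(w))
  else list(output = out, weights = w)
}

# full forward pass; X is batch x n_bands, returns standardized-scale
# predictions and (optionally) every intermediate needed for backprop
cnn_forward <- function(model, X, keep_cache = FALSE) {
  p <- model$params
  cfg <- model$cfg
  B <- nrow(X)
  cache <- list()
  if (cfg$attention) {
    z1 <- fc_forward(X, p$se_W1, p$se_b1)
    h1 <- relu(z1)
    z2 <- fc_forward(h1, p$se_W2, p$se_b2)
    w <- sigmoid(z2)
    Xg <- w * X
    if (keep_cache) cache$se <- list(z1 = z1, h1 = h1, w = w, X = X)
  } else {
    w <- NULL
    Xg <- X
  }
  X3 <- array(Xg, c(B, 1L, cfg$n_bands))  # column-major: batch fastest
  st <- conv1d_forward(X3, p$stem_W, p$stem_b, cfg$stem_kernel, 2L,
                       model$dims$stem_pl, model$dims$stem_pr)
  a_st <- relu(st$out)
  pooled <- avgpool_forward(a_st, 3L)
  b1 <- conv1d_forward(pooled, p$inc1_W, p$inc1_b, 1L, 1L, 0L, 0L)
  b3 <- conv1d_forward(pooled, p$inc3_W, p$inc3_b, 3L, 1L, 1L, 1L)
  b5 <- conv1d_forward(pooled, p$inc5_W, p$inc5_b, 5L, 1L, 2L, 2L)
  pp <- avgpool_same3_forward(pooled)
  bp <- conv1d_forward(pp, p$incp_W, p$incp_b, 1L, 1L, 0L, 0L)
  C2 <- cfg$inception_channels
  L <- model$dims$pooled_len
  cat4 <- array(0, c(B, 4L * C2, L))
  cat4[, 1:C2, ] <- relu(b1$out)
  cat4[, C2 + 1:C2, ] <- relu(b3$out)
  cat4[, 2L * C2 + 1:C2, ] <- relu(b5$out)
  cat4[, 3L * C2 + 1:C2, ] <- relu(bp$out)
  flat <- cat4
  dim(flat) <- c(B, 4L * C2 * L)
  h_fc <- relu(fc_forward(flat, p$fc1_W, p$fc1_b))
  pred <- drop(fc_forward(h_fc, p$fc2_W, p$fc2_b))
  if (keep_cache) {
    cache$X3 <- X3; cache$st <- st; cache$a_st <- a_st
    cache$pooled <- pooled
    cache$b1 <- b1; cache$b3 <- b3; cache$b5 <- b5
    cache$pp <- pp; cache$bp <- bp
    cache$cat4 <- cat4; cache$flat <- flat; cache$h_fc <- h_fc
  }
  list(pred = pred, weights = w, cache = cache)
}

# backward pass; dpred is the gradient of the loss w.r.t. the predictions
cnn_backward <- function(model, fw, dpred) {
  p <- model$params
  cfg <- model$cfg
  ch <- fw$cache
  B <- nrow(ch$flat)
  g <- list()
  dpred <- matrix(dpred, B, 1L)
  fb2 <- fc_backward(dpred, ch$h_fc, p$fc2_W)
  g$fc2_W <- fb2$dW; g$fc2_b <- fb2$db
  dh <- fb2$dX * (ch$h_fc > 0)
  fb1 <- fc_backward(dh, ch$flat, p$fc1_W)
  g$fc1_W <- fb1$dW; g$fc1_b <- fb1$db
  C2 <- cfg$inception_channels
  L <- model$dims$pooled_len
  dcat <- fb1$dX
  dim(dcat) <- c(B, 4L * C2, L)
  d1 <- dcat[, 1:C2, , drop = FALSE] * (ch$b1$out > 0)
  d3 <- dcat[, C2 + 1:C2, , drop = FALSE] * (ch$b3$out > 0)
  d5 <- dcat[, 2L * C2 + 1:C2, , drop = FALSE] * (ch$b5$out > 0)
  dp <- dcat[, 3L * C2 + 1:C2, , drop = FALSE] * (ch$bp$out > 0)
  cb1 <- conv1d_backward(d1, p$inc1_W, ch$b1$cache)
  cb3 <- conv1d_backward(d3, p$inc3_W, ch$b3$cache)
  cb5 <- conv1d_backward(d5, p$inc5_W, ch$b5$cache)
  cbp <- conv1d_backward(dp, p$incp_W, ch$bp$cache)
  g$inc1_W <- cb1$dW; g$inc1_b <- cb1$db
  g$inc3_W <- cb3$dW; g$inc3_b <- cb3$db
  g$inc5_W <- cb5$dW; g$inc5_b <- cb5$db
  g$incp_W <- cbp$dW; g$incp_b <- cbp$db
  dpooled <- cb1$dX + cb3$dX + cb5$dX + avgpool_same3_backward(cbp$dX)
  da <- avgpool_backward(dpooled, 3L, model$dims$stem_len)
  dst <- da * (ch$st$out > 0)
  cbs <- conv1d_backward(dst, p$stem_W, ch$st$cache)
  g$stem_W <- cbs$dW; g$stem_b <- cbs$db
  dX3 <- cbs$dX                       # (B, 1, n_bands)
  dXg <- matrix(aperm(dX3, c(1L, 3L, 2L)), B, cfg$n_bands)
  if (cfg$attention) {
    se <- ch$se
    dXdirect <- dXg * se$w
    dw <- dXg * se$X
    dz2 <- dw * se$w * (1 - se$w)
    fbse2 <- fc_backward(dz2, se$h1, p$se_W2)
    g$se_W2 <- fbse2$dW; g$se_b2 <- fbse2$db
    dz1 <- fbse2$dX * (se$z1 > 0)
    fbse1 <- fc_backward(dz1, se$X, p$se_W1)
    g$se_W1 <- fbse1$dW; g$se_b1 <- fbse1$db
    # gate path gradient into the input is not needed (inputs are data)
  }
  g
}

#' Cosine-annealed learning rate with warm restarts
#'
#' \deqn{lr(e) = lr_{min} + (lr_{max} - lr_{min}) (1 + \cos(\pi (e \bmod T)/T))/2}
#' with period `T = cfg$lr_restart`, so the rate decays from
#' `cfg$learning_rate` to `cfg$lr_min` and is reset every `T` epochs.
#'
#' @param epoch zero-based epoch index, `0 <= epoch < cfg$epochs`.
#' @param cfg a [model_config()].
#' @return The learning rate for that epoch.
#' @export
cosine_annealing_lr <- function(epoch, cfg) {
  if (any(epoch < 0) || any(epoch >= cfg$epochs))
    stop("'epoch' must lie in [0, epochs)")
  t <- epoch %% cfg$lr_restart
  cfg$lr_min + 0.5 * (cfg$learning_rate - cfg$lr_min) *
    (1 + cos(pi * t / cfg$lr_restart))
}

#' Train the spectral attention CNN
#'
#' Minimizes mean squared error plus an L2 penalty on the weight matrices
#' with the Adam optimizer, under a cosine-annealed learning rate with warm
#' restarts. Offset/slope augmentation is applied to training minibatches
#' only; the validation set (if any) is used purely for monitoring and
#' never influences the parameters. The response is internally centred and
#' scaled during optimization and predictions are mapped back to SPAD
#' units. The whole run is reproducible given `cfg$seed`.
#'
#' @param model an untrained (or previously trained) [build_model()] result.
#' @param x `n x n_bands` matrix of (min-max scaled) spectra.
#' @param y numeric response (SPAD), length `n`.
#' @param x_val,y_val optional held-out set for loss monitoring.
#' @param cfg a [model_config()]; defaults to the model's own.
#' @return List with `model` (trained) and `history` (data frame with one
#'   row per epoch: `epoch`, `train_loss`, `val_loss` — mean squared errors
#'   in SPAD squared units — and `lr`).
#' @export
train_cnn <- function(model, x, y, x_val = NULL, y_val = NULL,
                      cfg = model$cfg) {
  if (!inherits(model, "spad_cnn")) stop("'model' must be a spad_cnn")
  if (!is.matrix(x) || nrow(x) == 0L) stop("'x' must be a non-empty matrix")
  if (ncol(x) != cfg$n_bands)
    stop(sprintf("spectra have %d bands, model expects %d", ncol(x), cfg$n_bands))
  if (length(y) != nrow(x)) stop("'y' must have one value per row of 'x'")
  if (!is.null(x_val) && ncol(x_val) != cfg$n_bands)
    stop("validation spectra length mismatch")
  n <- nrow(x)
  if (cfg$standardize_y) {
    y_center <- mean(y)
    y_scale <- stats::sd(y)
    if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  } else {
    y_center <- 0; y_scale <- 1
  }
  ys <- (y - y_center) / y_scale
  ys_val <- if (!is.null(y_val)) (y_val - y_center) / y_scale
  weight_names <- grep("_W$", names(model$params), value = TRUE)
  adam_m <- lapply(model$params, function(p) p * 0)
  adam_v <- lapply(model$params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  sds <- apply(x, 1L, stats::sd)
  acfg <- cfg$augment_cfg
  history <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                        val_loss = NA_real_, lr = NA_real_)
  params <- model$params
  run <- function() {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cosine_annealing_lr(epoch - 1L, cfg)
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      ep_n <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        Xb <- x[idx, , drop = FALSE]
        if (cfg$augment) {
          B <- length(idx)
          a <- stats::runif(B, acfg$slope_low, acfg$slope_high)
          off <- stats::runif(B, -acfg$offset_factor * sds[idx],
                              acfg$offset_factor * sds[idx])
          Xb <- Xb * a + off
        }
        fw <- cnn_forward(list(params = params, cfg = cfg, dims = model$dims),
                          Xb, keep_cache = TRUE)
        diff <- fw$pred - ys[idx]
        mse <- mean(diff^2)
        grads <- cnn_backward(list(params = params, cfg = cfg,
                                   dims = model$dims), fw,
                              2 * diff / length(idx))
        step <<- step + 1L
        for (nm in names(params)) {
          gr <- grads[[nm]]
          if (cfg$l2 > 0 && nm %in% weight_names)
            gr <- gr + 2 * cfg$l2 * params[[nm]]
          adam_m[[nm]] <<- beta1 * adam_m[[nm]] + (1 - beta1) * gr
          adam_v[[nm]] <<- beta2 * adam_v[[nm]] + (1 - beta2) * gr^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          params[[nm]] <<- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + mse * length(idx)
        ep_n <- ep_n + length(idx)
      }
      history$train_loss[epoch] <<- ep_loss / ep_n * y_scale^2
      history$lr[epoch] <<- lr
      if (!is.null(x_val)) {
        pv <- cnn_forward(list(params = params, cfg = cfg, dims = model$dims),
                          x_val)$pred
        history$val_loss[epoch] <<- mean((pv - ys_val)^2) * y_scale^2
      }
    }
  }
  with_seed(cfg$seed, run())
  model$params <- params
  model$y_center <- y_center
  model$y_scale <- y_scale
  model$trained <- TRUE
  list(model = model, history = history)
}

#' Predict SPAD values from spectra
#'
#' @param object a `"spad_cnn"` model.
#' @param newdata spectrum vector of length `n_bands` or a
#'   `samples x n_bands` matrix, min-max scaled like the training spectra.
#' @param ... unused.
#' @return Numeric vector of SPAD estimates (a scalar for a single
#'   spectrum). Batched and one-at-a-time calls agree row by row.
#' @export
predict.spad_cnn <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (ncol(X) != object$cfg$n_bands)
    stop(sprintf("spectra have %d bands, model expects %d",
                 ncol(X), object$cfg$n_bands))
  if (any(!is.finite(X))) stop("input spectra contain non-finite values")
  raw <- cnn_forward(object, X)$pred
  drop(object$y_scale * raw + object$y_center)
}

#' Mean attention weights over a set of spectra
#'
#' Runs the spectral attention gate on each spectrum and averages the
#' per-band sigmoid weights; the usual way to inspect which wavelengths the
#' trained network considers informative.
#'
#' @param model a `"spad_cnn"` model with attention enabled.
#' @param spectra `samples x n_bands` matrix (or a single spectrum vector).
#' @return Numeric vector of length `n_bands`, each value in (0, 1).
#' @export
get_attention_weights <- function(model, spectra) {
  if (!inherits(model, "spad_cnn")) stop("'model' must be a spad_cnn")
  if (!model$cfg$attention) stop("model was built without an attention gate")
  X <- if (is.matrix(spectra)) spectra else matrix(spectra, nrow = 1L)
  if (nrow(X) == 0L) stop("'spectra' is empty")
  w <- se_recalibrate(X, model$params)$weights
  if (!is.matrix(w)) w else colMeans(w)
}
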