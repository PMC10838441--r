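#' Shuffled k-fold assignment
#'
#' Randomly partitions `n` samples into `k` folds whose sizes differ by at
#' most one (e.g. 478 samples into five folds of 96, 96, 96, 95 and 95).
#' Deterministic for a given seed; the global RNG state is preserved.
#'
#' @param n number of samples, `n >= k`.
#' @param k number of folds, `k >= 2`.
#' @param seed integer seed.
#' @return Integer vector of length `n` with fold labels in `1..k`.
#' @export
kfold_split <- function(n, k = 5, seed = 1) {
  if (k < 2) stop("'k' must be at least 2")
  if (n < k) stop(sprintf("'n' (%d) must be at least 'k' (%d)", n, k))
  with_seed(seed, {
    folds <- rep(seq_len(k), length.out = n)
    folds[sample.int(n)]
  })
}

#' Regression metrics: RMSE, NRMSE and the coefficient of determination
#'
#' \deqn{RMSE = \sqrt{\tfrac1n \sum_i (y_i - k_i)^2}}
#' \deqn{NRMSE = RMSE / \bar y}
#' \deqn{R^2 = 1 - \sum_i (y_i - k_i)^2 / \sum_i (y_i - \bar y)^2}
#' with \eqn{y_i} the ground truth, \eqn{k_i} the predictions and
#' \eqn{\bar y} the mean of the ground truth. Note NRMSE is normalized by
#' the mean of the truth, not by its range.
#'
#' @param y_true ground-truth values (non-constant, non-zero mean).
#' @param y_pred predictions, same length.
#' @return List with elements `rmse`, `nrmse` and `r2`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' must have equal, non-zero length")
  ybar <- mean(y_true)
  ss_res <- sum((y_true - y_pred)^2)
  ss_tot <- sum((y_true - ybar)^2)
  if (ss_tot == 0) stop("R2 is undefined for a constant 'y_true'")
  if (ybar == 0) stop("NRMSE is undefined when mean(y_true) is zero")
  rmse <- sqrt(ss_res / length(y_true))
  list(rmse = rmse, nrmse = rmse / ybar, r2 = 1 - ss_res / ss_tot)
}

# internal: tune the PLSR component count by inner cross-validation,
# exploiting that one fit at max_comp yields predictions at every smaller
# component count; ties break toward fewer components
tune_plsr_ncomp <- function(X, y, max_comp, k = 5, seed = 1) {
  folds <- kfold_split(nrow(X), k, seed = seed)
  # components cannot exceed what the smallest inner training split supports
  smallest_train <- nrow(X) - max(tabulate(folds, k))
  max_comp <- max(1L, min(max_comp, smallest_train - 2L, ncol(X)))
  err2 <- numeric(max_comp)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- mixOmics::pls(X[tr, , drop = FALSE], y[tr], ncomp = max_comp,
                         mode = "regression")
    pr <- stats::predict(fit, X[!tr, , drop = FALSE])$predict[, 1L, ]
    pr <- matrix(pr, ncol = max_comp)
    err2 <- err2 + colSums((y[!tr] - pr)^2)
  }
  which.min(err2)
}

#' Cross-validated benchmark of one estimation method
#'
#' Runs the full k-fold protocol for any of the pipeline's methods: within
#' each split the model (including every data-dependent choice — PLSR
#' component tuning, SPA wavelength selection, spectral augmentation,
#' response standardization) is fitted on the training folds only and
#' scored on the held-out fold with [compute_metrics()]. Within a split the
#' SPA wavelengths are shared between the PLSR and RF arms (both arms
#' re-select on the same training data with the same internal seed, which
#' yields identical subsets).
#'
#' Methods:
#' \describe{
#'   \item{`cnn_attention`}{the spectral attention CNN.}
#'   \item{`cnn_plain`}{the same network with the attention gate ablated.}
#'   \item{`plsr_full`, `rf_full`}{PLSR / random forest on the full spectrum.}
#'   \item{`plsr_spa`, `rf_spa`}{PLSR / RF on SPA-selected bands.}
#'   \item{`plsr_spa_fdr`, `rf_spa_fdr`}{PLSR / RF on SPA-selected bands of
#'     the first-derivative spectra.}
#' }
#'
#' @param dataset a [generate_dataset()] result, or any list with elements
#'   `spectra` (samples x bands matrix), `spad` (response) and
#'   `wavelengths`.
#' @param method one of the method keys above.
#' @param config optional named list of overrides: `k` (folds, default 5),
#'   `epochs`, `batch_size`, `learning_rate`, `l2`, `augment` (CNN);
#'   `max_components` (PLSR tuning ceiling, default 15); `n_trees` (RF,
#'   default 1500); `spa_sizes` (default `3:15`).
#' @param seed integer seed governing the fold split and all per-fold
#'   stochastic stages.
#' @return A data frame of class `"cv_result"` with one row per fold plus a
#'   final `"Average"` row, columns `fold`, `rmse`, `nrmse`, `r2`. Per-fold
#'   held-out predictions are attached as attribute `"predictions"`.
#' @export
run_cv <- function(dataset, method, config = list(), seed = 1) {
  methods <- c("cnn_attention", "cnn_plain", "plsr_full", "rf_full",
               "plsr_spa", "rf_spa", "plsr_spa_fdr", "rf_spa_fdr")
  if (!is.character(method) || length(method) != 1L || !(method %in% methods))
    stop(sprintf("unknown method '%s'; expected one of: %s",
                 paste(method, collapse = ","), paste(methods, collapse = ", ")))
  spectra <- dataset$spectra
  y <- dataset$spad
  wl <- dataset$wavelengths
  n <- nrow(spectra)
  k <- config$k %||% 5
  folds <- kfold_split(n, k, seed = seed)

  use_fdr <- grepl("_fdr$", method)
  base_x <- if (use_fdr) first_derivative(spectra, wl) else spectra
  X <- minmax_scale(base_x)           # per-sample scaling: no leakage
  colnames(X) <- colnames(spectra)

  rows <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    Xva <- X[!tr, , drop = FALSE]
    ytr <- y[tr]
    fold_seed <- seed * 1000L + f
    pv <- switch(sub("_(full|spa|spa_fdr)$", "", method),
      cnn_attention = ,
      cnn_plain = {
        cfg <- model_config(
          n_bands = ncol(X),
          epochs = config$epochs %||% 500,
          batch_size = config$batch_size %||% 6,
          learning_rate = config$learning_rate %||% 1e-4,
          l2 = config$l2 %||% 1e-4,
          augment = config$augment %||% TRUE,
          attention = method == "cnn_attention",
          seed = fold_seed)
        fit <- train_cnn(build_model(cfg), Xtr, ytr)
        predict(fit$model, Xva)
      },
      plsr = {
        sel <- seq_len(ncol(X))
        if (grepl("spa", method)) {
          spa <- spa_select(Xtr, ytr, size_range = config$spa_sizes %||% 3:15,
                            seed = fold_seed)
          sel <- spa$selected
        }
        nc <- tune_plsr_ncomp(Xtr[, sel, drop = FALSE], ytr,
                              max_comp = config$max_components %||% 15,
                              seed = fold_seed)
        m <- fit_plsr(Xtr[, sel, drop = FALSE], ytr, n_components = nc)
        predict_plsr(m, Xva[, sel, drop = FALSE])
      },
      rf = {
        sel <- seq_len(ncol(X))
        if (grepl("spa", method)) {
          spa <- spa_select(Xtr, ytr, size_range = config$spa_sizes %||% 3:15,
                            seed = fold_seed)
          sel <- spa$selected
        }
        m <- fit_rf(Xtr[, sel, drop = FALSE], ytr,
                    n_trees = config$n_trees %||% 1500, seed = fold_seed)
        predict_rf(m, Xva[, sel, drop = FALSE])
      }
    )
    met <- compute_metrics(y[!tr], pv)
    rows[[f]] <- data.frame(fold = as.character(f), rmse = met$rmse,
                            nrmse = met$nrmse, r2 = met$r2)
    preds[[f]] <- data.frame(fold = f, y = y[!tr], pred = pv)
  }
  tab <- do.call(rbind, rows)
  avg <- data.frame(fold = "Average", rmse = mean(tab$rmse),
                    nrmse = mean(tab$nrmse), r2 = mean(tab$r2))
  out <- rbind(tab, avg)
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "predictions") <- do.call(rbind, preds)
  class(out) <- c("cv_result", "data.frame")
  out
}

# tidyverse-style default helper (not exported)
`%||%` <- function(a, b) if (is.null(a)) b else a
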