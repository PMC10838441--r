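# Classical comparators: partial least squares regression, random forest,
# and successive-projections wavelength selection. PLSR and RF are thin
# wrappers over mixOmics and randomForest; the successive projections
# algorithm is implemented here (no installed package provides it).

# internal: ensure predictor matrix is usable
check_X <- function(X, y = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (anyNA(X)) stop("'X' must not contain missing values")
  if (all(apply(X, 2L, stats::sd) == 0))
    stop("'X' is degenerate: every column has zero variance")
  if (!is.null(y)) {
    if (anyNA(y)) stop("'y' must not contain missing values")
    if (length(y) != nrow(X)) stop("'y' must have one value per row of 'X'")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  X
}

#' Fit a partial least squares regression model
#'
#' Latent-variable linear regression for collinear spectra, delegated to
#' \pkg{mixOmics} in regression mode. With `n_components` equal to the rank
#' of `X`, predictions coincide with ordinary least squares.
#'
#' @param X `n x p` predictor matrix (band reflectances).
#' @param y numeric response (SPAD).
#' @param n_components number of latent components,
#'   `1 <= n_components <= min(n - 1, p)`.
#' @return An object of class `"plsr_model"`.
#' @export
fit_plsr <- function(X, y, n_components) {
  X <- check_X(X, y)
  if (stats::sd(y) == 0) {
    # degenerate but well-defined: constant response, constant prediction
    return(structure(list(constant = y[1], n_components = 0L,
                          colnames = colnames(X)),
                     class = "plsr_model"))
  }
  if (n_components < 1 || n_components > min(nrow(X) - 1L, ncol(X)))
    stop("'n_components' must lie in [1, min(n - 1, p)]")
  fit <- mixOmics::pls(X, y, ncomp = n_components, mode = "regression")
  structure(list(fit = fit, n_components = as.integer(n_components),
                 colnames = colnames(X)),
            class = "plsr_model")
}

#' @rdname fit_plsr
#' @param model a `"plsr_model"`.
#' @param newdata matrix with the same columns as the training `X`.
#' @param n_components predict with a smaller component count than fitted
#'   (defaults to the fitted count).
#' @export
predict_plsr <- function(model, newdata, n_components = model$n_components) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (!is.null(model$constant)) return(rep(model$constant, nrow(newdata)))
  colnames(newdata) <- model$colnames
  pr <- stats::predict(model$fit, newdata)
  as.numeric(pr$predict[, 1L, n_components])
}

#' Fit a random forest regressor
#'
#' Bagged regression trees via \pkg{randomForest}; 1500 trees by default
#' (the tree count a grid search typically settles on for spectra of this
#' kind). Reproducible under `seed`.
#'
#' @param X `n x p` predictor matrix.
#' @param y numeric response.
#' @param n_trees number of trees (default 1500).
#' @param seed optional integer seed (global RNG state preserved).
#' @return An object of class `"rf_model"`.
#' @export
fit_rf <- function(X, y, n_trees = 1500, seed = NULL) {
  if (NROW(X) < 2L) stop("random forest needs at least 2 samples")
  X <- check_X(X, y)
  if (n_trees < 1) stop("'n_trees' must be at least 1")
  fit <- with_seed(seed,
                   randomForest::randomForest(X, y, ntree = as.integer(n_trees)))
  structure(list(fit = fit, colnames = colnames(X)), class = "rf_model")
}

#' @rdname fit_rf
#' @param model an `"rf_model"`.
#' @param newdata matrix with the same columns as the training `X`.
#' @export
predict_rf <- function(model, newdata) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  colnames(newdata) <- model$colnames
  as.numeric(stats::predict(model$fit, newdata))
}

# internal: one SPA chain — successive projections from a start column.
# Xc is the column-centred predictor matrix; returns column indices in
# selection order. At each step the candidate with the largest norm after
# projection onto the orthogonal complement of the selected span is added
# (classical modified Gram-Schmidt sweep).
spa_chain <- function(Xc, start, max_size) {
  p <- ncol(Xc)
  R <- Xc                      # residuals of all columns w.r.t. selected span
  sel <- integer(0)
  cur <- start
  for (step in seq_len(max_size)) {
    sel <- c(sel, cur)
    v <- R[, cur]
    nv2 <- sum(v^2)
    if (nv2 <= .Machine$double.eps) break
    R <- R - v %*% crossprod(v, R) / nv2
    if (length(sel) == max_size) break
    norms <- colSums(R^2)
    norms[sel] <- -Inf
    cur <- unname(which.max(norms))
    if (norms[cur] <= 1e-12 * nv2) break
  }
  unname(sel)
}

# internal: cross-validated calibration RMSE of a band subset. The default
# calibrator is PLSR with as many components as selected bands, which for
# these small full-rank subsets coincides with least squares — so it is
# evaluated by least squares directly for speed.
spa_cv_rmse <- function(X, y, subset, folds) {
  err2 <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    Xt <- cbind(1, X[tr, subset, drop = FALSE])
    co <- stats::lm.fit(Xt, y[tr])$coefficients
    co[is.na(co)] <- 0
    pv <- cbind(1, X[!tr, subset, drop = FALSE]) %*% co
    err2 <- err2 + sum((y[!tr] - pv)^2)
  }
  sqrt(err2 / length(y))
}

#' Successive projections algorithm for wavelength selection
#'
#' Forward selection of minimally collinear bands: starting from each
#' candidate column in turn, the band whose residual (after orthogonal
#' projection onto the span of the already-selected bands) has maximal norm
#' is added repeatedly, giving one nested chain per start. Every prefix of
#' every chain with size in `size_range` is scored by cross-validated
#' calibration RMSE, and the best-scoring subset is returned.
#'
#' The default calibrator is PLSR using as many latent components as
#' selected bands, which for these small well-conditioned subsets equals
#' least squares and is computed as such. Supply `calibrator` to score
#' subsets differently.
#'
#' @param X `n x p` predictor matrix (column-centred internally).
#' @param y numeric response.
#' @param size_range candidate subset sizes (default `3:15`).
#' @param calibrator optional `function(X_train, y_train, X_new)` returning
#'   predictions, used to score subsets instead of the default.
#' @param n_folds folds of the internal scoring split (default 5).
#' @param seed seed for the internal scoring split (default 1).
#' @return An object of class `"spa_result"`: list with `selected` (band
#'   indices, in selection order), `size` (chosen subset size), `start`
#'   (chain start column), `rmse` (score of the chosen subset) and
#'   `error_curve` (best score per subset size).
#' @export
spa_select <- function(X, y, size_range = 3:15, calibrator = NULL,
                       n_folds = 5, seed = 1) {
  X <- check_X(X, y)
  p <- ncol(X)
  size_range <- sort(unique(as.integer(size_range)))
  if (min(size_range) < 1 || max(size_range) > p)
    stop(sprintf("'size_range' must lie within [1, %d]", p))
  max_size <- max(size_range)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  folds <- kfold_split(nrow(X), n_folds, seed = seed)
  score <- if (is.null(calibrator)) {
    function(subset) spa_cv_rmse(X, y, subset, folds)
  } else {
    function(subset) {
      err2 <- 0
      for (f in sort(unique(folds))) {
        tr <- folds != f
        pv <- calibrator(X[tr, subset, drop = FALSE], y[tr],
                         X[!tr, subset, drop = FALSE])
        err2 <- err2 + sum((y[!tr] - pv)^2)
      }
      sqrt(err2 / length(y))
    }
  }
  best <- list(rmse = Inf)
  error_curve <- rep(Inf, length(size_range))
  names(error_curve) <- size_range
  for (start in seq_len(p)) {
    chain <- spa_chain(Xc, start, max_size)
    for (si in seq_along(size_range)) {
      sz <- size_range[si]
      if (sz > length(chain)) next
      subset <- chain[seq_len(sz)]
      r <- score(subset)
      if (r < error_curve[si]) error_curve[si] <- r
      if (r < best$rmse ||
          (r == best$rmse && sz < best$size)) {
        best <- list(selected = subset, size = sz, start = start, rmse = r)
      }
    }
  }
  structure(c(best, list(error_curve = error_curve)), class = "spa_result")
}

#' @export
print.spa_result <- function(x, ...) {
  cat(sprintf("<spa_result> %d bands selected (start column %d), CV RMSE %.4f\n",
              x$size, x$start, x$rmse))
  cat(" indices:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Grid search over a single tuning parameter
#'
#' Scores each candidate value by mean validation RMSE over the supplied
#' fold assignment and returns the minimizer; ties go to the smaller
#' (simpler) value.
#'
#' @param method `"plsr"` (tunes the number of components) or `"rf"`
#'   (tunes the number of trees).
#' @param param_grid numeric vector of candidate values (non-empty).
#' @param X `n x p` predictor matrix.
#' @param y numeric response.
#' @param folds fold assignment from [kfold_split()].
#' @param seed seed forwarded to stochastic fits (RF).
#' @return List with `best` (chosen value) and `rmse` (named vector of mean
#'   validation RMSE per candidate).
#' @export
grid_search <- function(method = c("plsr", "rf"), param_grid, X, y, folds,
                        seed = 1) {
  method <- match.arg(method)
  if (length(param_grid) == 0L) stop("'param_grid' must be non-empty")
  X <- check_X(X, y)
  param_grid <- sort(unique(param_grid))
  fold_ids <- sort(unique(folds))
  rmse <- sapply(param_grid, function(val) {
    err2 <- 0
    for (f in fold_ids) {
      tr <- folds != f
      pv <- if (method == "plsr") {
        m <- fit_plsr(X[tr, , drop = FALSE], y[tr], n_components = val)
        predict_plsr(m, X[!tr, , drop = FALSE])
      } else {
        m <- fit_rf(X[tr, , drop = FALSE], y[tr], n_trees = val, seed = seed)
        predict_rf(m, X[!tr, , drop = FALSE])
      }
      err2 <- err2 + sum((y[!tr] - pv)^2)
    }
    sqrt(err2 / length(y))
  })
  names(rmse) <- param_grid
  list(best = param_grid[which.min(rmse)], rmse = rmse)
}
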