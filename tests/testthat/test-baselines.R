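test_that("PLSR recovers exact structure in the classical limits", {
  set.seed(8)
  # centred orthogonal design: one latent direction suffices when y is
  # proportional to a single column (PLSR centres internally, so the
  # columns must stay orthogonal after centring)
  Q <- qr.Q(qr(scale(matrix(rnorm(30 * 6), 30), scale = FALSE)))
  X <- Q %*% diag(seq(1, 2, length.out = 6))
  y <- 2 * X[, 4]
  m1 <- fit_plsr(X, y, n_components = 1)
  expect_equal(predict_plsr(m1, X), y, tolerance = 1e-8)

  # full component count reproduces ordinary least squares
  Xr <- matrix(rnorm(25 * 5), 25)
  yr <- rnorm(25)
  mfull <- fit_plsr(Xr, yr, n_components = 5)
  ols <- unname(fitted(lm(yr ~ Xr)))
  expect_equal(predict_plsr(mfull, Xr), ols, tolerance = 1e-8)

  # constant response predicts the constant
  mc <- fit_plsr(Xr, rep(4.2, 25), n_components = 2)
  expect_equal(predict_plsr(mc, Xr[1:3, ]), rep(4.2, 3))

  # training RMSE is non-increasing in the number of components
  rmse_at <- vapply(1:5, function(nc) {
    m <- fit_plsr(Xr, yr, n_components = nc)
    sqrt(mean((yr - predict_plsr(m, Xr))^2))
  }, numeric(1))
  expect_true(all(diff(rmse_at) <= 1e-10))

  expect_error(fit_plsr(matrix(1, 10, 3), rnorm(10), 2), "degenerate")
  expect_error(fit_plsr(Xr, yr, n_components = 30), "n_components")
})

test_that("random forest wrapper is seeded and honours the tree count", {
  set.seed(9)
  X <- matrix(rnorm(60 * 8), 60)
  y <- X[, 1] + rnorm(60, 0, 0.1)
  m1 <- fit_rf(X, y, n_trees = 100, seed = 7)
  m2 <- fit_rf(X, y, n_trees = 100, seed = 7)
  expect_identical(predict_rf(m1, X), predict_rf(m2, X))
  expect_equal(m1$fit$ntree, 100)

  # constant response: randomForest warns about regression on few unique
  # values but the prediction is still the constant
  mc <- suppressWarnings(fit_rf(X, rep(2.5, 60), n_trees = 50, seed = 1))
  expect_equal(predict_rf(mc, X[1:4, ]), rep(2.5, 4))

  expect_error(fit_rf(X[1, , drop = FALSE], y[1], seed = 1), "2 samples")
})

test_that("successive projections match an explicit Gram-Schmidt oracle", {
  set.seed(12)
  X <- matrix(rnorm(8 * 6), 8)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  for (start in 1:6) {
    expect_identical(chlorospec:::spa_chain(Xc, start, 5),
                     gs_spa_chain(Xc, start, 5))
  }

  # step 1 from an orthogonal matrix picks the largest-norm column
  Q <- qr.Q(qr(matrix(rnorm(20 * 5), 20)))
  Xo <- Q %*% diag(c(3, 1, 5, 2, 4))
  Xoc <- scale(Xo, center = TRUE, scale = FALSE)
  norms <- colSums(Xoc^2)
  expect_equal(chlorospec:::spa_chain(Xoc, which.max(norms), 1),
               which.max(norms))

  # an exact duplicate has zero projected norm once its twin is selected
  Xd <- cbind(X, X[, 3])
  chain <- chlorospec:::spa_chain(scale(Xd, scale = FALSE), 3, 7)
  pos3 <- which(chain == 3)
  if (7 %in% chain) expect_gt(which(chain == 7), pos3 + 1)
})

test_that("spa_select returns a nested, scored subset inside the range", {
  ds <- generate_dataset(80, seed = 13)
  X <- minmax_scale(ds$spectra)
  colnames(X) <- colnames(ds$spectra)
  res <- spa_select(X, ds$spad, size_range = 3:10, seed = 2)

  expect_s3_class(res, "spa_result")
  expect_length(res$selected, res$size)
  expect_true(res$size >= 3 && res$size <= 10)
  expect_false(anyDuplicated(res$selected) > 0)
  expect_equal(unname(res$error_curve[as.character(res$size)]), res$rmse)

  # prefix property: the chosen subset is the chain prefix from its start
  Xc <- scale(X, center = TRUE, scale = FALSE)
  chain <- chlorospec:::spa_chain(Xc, res$start, max(3:10))
  expect_identical(res$selected, chain[seq_len(res$size)])

  # selected bands concentrate where the generator puts the signal
  # (chlorophyll absorption plus red edge, 430-730 nm)
  wl <- ds$wavelengths[res$selected]
  expect_gte(mean(wl >= 430 & wl <= 730), 0.5)

  expect_error(spa_select(X, ds$spad, size_range = 3:500), "size_range")
})

test_that("grid search minimizes validation RMSE with simplicity ties", {
  set.seed(14)
  n <- 60
  # X is (almost) rank 2 and y lives in the latent plane, so components
  # beyond the true dimension only fit noise
  T2 <- matrix(rnorm(n * 2), n)
  P <- matrix(rnorm(2 * 12), 2)
  X <- T2 %*% P + matrix(rnorm(n * 12, 0, 0.02), n)
  y <- as.numeric(T2 %*% c(1.5, -1) + rnorm(n, 0, 0.1))
  folds <- kfold_split(n, 4, seed = 3)

  gs <- grid_search("plsr", 1:6, X, y, folds)
  expect_lte(gs$best, 3)  # true latent dimension is 2
  expect_length(gs$rmse, 6)

  # grid of one value returns that value; order of the grid is irrelevant
  expect_equal(grid_search("plsr", 4, X, y, folds)$best, 4)
  expect_equal(grid_search("plsr", c(5, 2, 3), X, y, folds)$best,
               grid_search("plsr", c(3, 5, 2), X, y, folds)$best)

  gs_rf <- grid_search("rf", c(20, 50), X, y, folds, seed = 5)
  expect_true(gs_rf$best %in% c(20, 50))

  expect_error(grid_search("plsr", numeric(0), X, y, folds), "non-empty")
})
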