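test_that("model skeleton has the declared shapes and parameter count", {
  cfg <- model_config()
  m <- build_model(cfg)

  # stem downsamples 180 -> 90 -> 30: exactly 1/6 of the input
  expect_equal(m$dims$stem_len, 90)
  expect_equal(m$dims$pooled_len, 30)
  expect_equal(m$dims$pooled_len / cfg$n_bands, 1 / 6)

  # hand-computed parameter count for the default configuration:
  # SE 180*45+45 + 45*180+180, stem 7*16+16, inception (1+3+5+1)*16*16+4*16,
  # fc 5760*... -> see below
  se <- 180 * 45 + 45 + 45 * 180 + 180
  stem <- 7 * 16 + 16
  inception <- (1 + 3 + 5 + 1) * 16 * 16 + 4 * 16
  fc <- (4 * 16 * 30) * 64 + 64 + 64 * 1 + 1
  expect_equal(count_parameters(m), se + stem + inception + fc)
  expect_equal(count_parameters(m), 142186)

  # inception output channels are the sum of the four branch widths
  X <- matrix(runif(2 * 180), 2)
  fw <- chlorospec:::cnn_forward(m, X, keep_cache = TRUE)
  expect_equal(dim(fw$cache$cat4), c(2, 4 * 16, 30))
  expect_equal(dim(fw$cache$st$out)[3], 90)

  # ablated variant drops exactly the attention parameters
  plain <- build_model(model_config(attention = FALSE))
  expect_equal(count_parameters(m) - count_parameters(plain), se)

  # deterministic initialization
  m2 <- build_model(cfg)
  expect_identical(m$params, m2$params)

  expect_error(model_config(n_bands = 100), "divisible by 6")
  expect_error(build_model(model_config(n_bands = 179)), "divisible")
})

test_that("squeeze-and-excitation gate behaves like a sigmoid reweighting", {
  m <- build_model(model_config(seed = 2))
  x <- runif(180)

  se <- se_recalibrate(x, m)
  expect_length(se$weights, 180)
  expect_true(all(se$weights > 0 & se$weights < 1))
  expect_equal(se$output, se$weights * x)

  # zero attention parameters force every gate to sigmoid(0) = 0.5
  zero <- lapply(m$params, function(p) p * 0)
  se0 <- se_recalibrate(x, zero)
  expect_equal(se0$weights, rep(0.5, 180))
  expect_equal(se0$output, 0.5 * x)

  # multiplicative gating: zero input stays zero
  expect_equal(se_recalibrate(numeric(180), m)$output, numeric(180))

  expect_error(se_recalibrate(runif(10), m), "length")
})

test_that("forward pass is consistent, deterministic and honest about NaN", {
  m <- build_model(model_config(seed = 3))
  X <- matrix(runif(5 * 180), 5)

  batch <- predict(m, X)
  single <- vapply(seq_len(5), function(i) predict(m, X[i, ]), numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
  expect_identical(predict(m, X), batch)  # no stochastic layers

  # all-zero parameters: output equals the final-layer bias
  m0 <- m
  m0$params <- lapply(m$params, function(p) p * 0)
  m0$params$fc2_b <- 0.37
  expect_equal(unname(predict(m0, X)), rep(0.37, 5))

  bad <- X
  bad[2, 7] <- NaN
  expect_error(predict(m, bad), "non-finite")
})

test_that("cosine annealing restarts the learning rate on schedule", {
  cfg <- model_config(epochs = 500, lr_restart = 200, learning_rate = 1e-4)
  expect_equal(cosine_annealing_lr(0, cfg), 1e-4)
  expect_equal(cosine_annealing_lr(200, cfg), 1e-4)
  expect_equal(cosine_annealing_lr(400, cfg), 1e-4)
  expect_equal(cosine_annealing_lr(100, cfg), 5e-5)
  expect_equal(cosine_annealing_lr(199, cfg),
               0.5e-4 * (1 + cos(pi * 199 / 200)))
  expect_error(cosine_annealing_lr(500, cfg), "epochs")
})

test_that("training memorizes a tiny noise-free set and descends", {
  set <- tiny_clean_set(6)
  cfg <- model_config(epochs = 500, augment = FALSE, seed = 5)
  fit <- train_cnn(build_model(cfg), set$x, set$y)

  expect_lt(tail(fit$history$train_loss, 1), 0.5)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_equal(nrow(fit$history), 500)
  expect_true(all(fit$history$lr > 0))

  # predictions recover the memorized labels closely
  expect_lt(max(abs(predict(fit$model, set$x) - set$y)), 2)
})

test_that("training is bit-reproducible and ignores validation labels", {
  ds <- generate_dataset(60, seed = 2)
  X <- minmax_scale(ds$spectra)
  cfg <- model_config(epochs = 3, seed = 9)

  f1 <- train_cnn(build_model(cfg), X[1:48, ], ds$spad[1:48],
                  x_val = X[49:60, ], y_val = ds$spad[49:60])
  f2 <- train_cnn(build_model(cfg), X[1:48, ], ds$spad[1:48],
                  x_val = X[49:60, ], y_val = ds$spad[49:60])
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)

  # poisoned validation labels leave the trained parameters bit-identical
  f3 <- train_cnn(build_model(cfg), X[1:48, ], ds$spad[1:48],
                  x_val = X[49:60, ], y_val = ds$spad[49:60] + 100)
  expect_identical(f1$model$params, f3$model$params)
  expect_false(identical(f1$history$val_loss, f3$history$val_loss))
})

test_that("trained attention concentrates on the absorption window", {
  ds <- generate_dataset(200, seed = 3)
  X <- minmax_scale(ds$spectra)
  wl <- ds$wavelengths
  fit <- train_cnn(build_model(model_config(epochs = 60, seed = 4)),
                   X, ds$spad)

  w <- get_attention_weights(fit$model, X)
  expect_length(w, 180)
  expect_true(all(w > 0 & w < 1))

  # the red chlorophyll absorption window outweighs a flat NIR window
  # that carries no label information in the generator
  absorb <- wl >= 630 & wl <= 695
  flat <- wl >= 800 & wl <= 900
  expect_gt(mean(w[absorb]), mean(w[flat]))

  # averaging a single spectrum returns its own gate vector
  expect_equal(get_attention_weights(fit$model, X[1, ]),
               se_recalibrate(X[1, ], fit$model)$weights)
  expect_error(get_attention_weights(fit$model, X[0, , drop = FALSE]),
               "empty")
  plain <- build_model(model_config(attention = FALSE))
  expect_error(get_attention_weights(plain, X), "attention")
})
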