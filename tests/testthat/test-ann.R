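test_that("z-score scaler: definition, round trip, leak guard", {
  d <- data.frame(a = c(1, 2, 3, 4), b = c(10, 20, 30, 40))
  sc <- zscore_fit(d)
  expect_equal(zscore_apply(sc, data.frame(a = mean(d$a), b = mean(d$b)))$a, 0)
  expect_equal(zscore_apply(sc, data.frame(a = mean(d$a) + sd(d$a),
                                           b = mean(d$b)))$a, 1)
  back <- zscore_invert(sc, zscore_apply(sc, d))
  expect_equal(as.data.frame(back), d, tolerance = 1e-12)
  expect_error(zscore_fit(data.frame(a = rep(1, 5))),
               class = "atheromech_domain_error")
})

test_that("dataset split is disjoint, exhaustive, and seed-stable", {
  d <- data.frame(i = 1:1000, x = rnorm(1000))
  sp <- split_dataset(d, c(0.8, 0.1, 0.1), seed = 5)
  expect_equal(nrow(sp$train), 800)
  expect_equal(nrow(sp$validation), 100)
  expect_equal(nrow(sp$test), 100)
  all_i <- c(sp$train$i, sp$validation$i, sp$test$i)
  expect_setequal(all_i, d$i)
  expect_equal(anyDuplicated(all_i), 0)
  sp2 <- split_dataset(d, c(0.8, 0.1, 0.1), seed = 5)
  expect_identical(sp$train$i, sp2$train$i)
  expect_error(split_dataset(d[1:5, ], seed = 1), class = "atheromech_domain_error")
  expect_error(split_dataset(d, c(0.5, 0.4, 0.2), seed = 1),
               class = "atheromech_domain_error")
})

test_that("the 14-layer default architecture is wired as specified", {
  spec <- mlp_spec()
  expect_equal(spec$n_layers, 14)
  expect_equal(spec$layer_sizes[1], 4)
  expect_equal(spec$layer_sizes[length(spec$layer_sizes)], 2)
  expect_length(spec$layer_sizes, 14)
})

test_that("forward pass matches a brute-force matrix chain", {
  p <- atheromech:::mlp_init(mlp_spec(3, c(7, 5), 2), seed = 21)
  X <- matrix(rnorm(30), 10, 3)
  manual <- X
  for (l in 1:3) {
    manual <- manual %*% p$W[[l]]
    manual <- sweep(manual, 2, p$b[[l]], "+")
    if (l < 3) manual <- pmax(manual, 0)
  }
  expect_equal(mlp_forward(p, X), manual, tolerance = 1e-12)
  # ReLU basics via a hand-built single neuron
  one <- list(W = list(matrix(1), matrix(1)), b = list(0, 0))
  expect_equal(mlp_forward(one, matrix(c(-1, 2), 2, 1)), matrix(c(0, 2), 2, 1))
  expect_error(mlp_forward(p, matrix(0, 2, 5)), class = "atheromech_shape_error")
})

test_that("backpropagation matches finite differences of the loss", {
  set.seed(6)
  p <- atheromech:::mlp_init(mlp_spec(3, c(6, 4), 2), seed = 3)
  X <- matrix(rnorm(24), 8, 3)
  Y <- matrix(rnorm(16), 8, 2)
  As <- atheromech:::mlp_forward_cached(p, X)
  g <- atheromech:::mlp_backward(p, As, Y)
  h <- 1e-6
  for (probe in list(c(1, 2, 3), c(2, 4, 1), c(3, 1, 2))) {
    l <- probe[1]; i <- probe[2]; j <- probe[3]
    pp <- p; pm <- p
    pp$W[[l]][i, j] <- pp$W[[l]][i, j] + h
    pm$W[[l]][i, j] <- pm$W[[l]][i, j] - h
    fd <- (atheromech:::mse_of(pp, X, Y) - atheromech:::mse_of(pm, X, Y)) / (2 * h)
    expect_equal(g$dW[[l]][i, j], fd, tolerance = 1e-6)
  }
})

test_that("training drives the identity map to machine-level loss", {
  set.seed(3)
  X <- matrix(rnorm(200), 100, 2)
  spec <- mlp_spec(n_in = 2, hidden = 16, n_out = 2)
  cfg <- train_config(epochs = 4000, lr = 1e-2, milestones = c(2000, 3000),
                      batch_size = 16, seed = 4)
  fit <- atheromech:::train_mlp_matrices(X, X, NULL, NULL, spec, cfg)
  expect_lt(tail(fit$history$train_mse, 1), 1e-8)
})

test_that("training is deterministic for a fixed seed", {
  set.seed(8)
  X <- matrix(rnorm(120), 60, 2)
  Y <- X %*% matrix(c(1, 0.5, -0.3, 2), 2)
  spec <- mlp_spec(2, c(8, 8), 2)
  cfg <- train_config(epochs = 50, milestones = 40, batch_size = 16, seed = 7)
  f1 <- atheromech:::train_mlp_matrices(X, Y, NULL, NULL, spec, cfg)
  f2 <- atheromech:::train_mlp_matrices(X, Y, NULL, NULL, spec, cfg)
  expect_identical(f1$params$W, f2$params$W)
  expect_identical(f1$history$train_mse, f2$history$train_mse)
})

test_that("end-to-end training on a toy dataset records losses and scales", {
  ds <- toy_dataset(n = 300)
  cfg <- train_config(epochs = 120, milestones = c(60, 100), batch_size = 64,
                      seed = 2)
  model <- train_stiffness_model(ds, spec = mlp_spec(hidden = rep(8, 12)),
                                 config = cfg)
  expect_equal(nrow(model$history), 120)
  expect_true(all(is.finite(model$history$val_mse)))
  # scaler statistics derive from training rows only (targets are
  # log10-transformed before scaling by default)
  tr_rows <- tibble::as_tibble(ds)[model$split_indices$train, ]
  expect_equal(unname(model$y_scaler$mu["E_core"]), mean(log10(tr_rows$E_core)),
               tolerance = 1e-12)
  expect_equal(unname(model$x_scaler$sigma["SR"]), sd(tr_rows$SR),
               tolerance = 1e-12)
})

test_that("evaluation reports per-case relative errors in physical units", {
  ds <- toy_dataset(n = 120)
  cfg <- train_config(epochs = 60, milestones = 50, batch_size = 64, seed = 2)
  model <- train_stiffness_model(ds, spec = mlp_spec(hidden = rep(8, 12)),
                                 config = cfg)
  rep <- evaluate(model, ds)
  expect_true(all(rep$cases$err_E_core >= 0))
  expect_true(all(rep$cases$err_E_plaque >= 0))
  # aggregate equals a hand-computed mean of per-case errors
  expect_equal(rep$summary$mean[rep$summary$target == "E_core"],
               mean(rep$cases$err_E_core), tolerance = 1e-12)
  # a perfect prediction gives zero error (direct formula check)
  expect_equal(abs(97 - 100) / 100 * 100, 3)
})

test_that("predictions preserve order and flag extrapolation", {
  ds <- toy_dataset(n = 120)
  cfg <- train_config(epochs = 40, milestones = 30, batch_size = 64, seed = 2)
  model <- train_stiffness_model(ds, spec = mlp_spec(hidden = rep(8, 12)),
                                 config = cfg)
  feats <- tibble::as_tibble(ds)[1:7, ]
  pred <- predict_properties(model, feats)
  expect_equal(nrow(pred), 7)
  expect_named(pred, c("E_core", "E_plaque", "out_of_range"))
  far <- feats[1, ]
  far$SR <- 1e4
  expect_warning(predict_properties(model, far),
                 class = "atheromech_extrapolation")
})

test_that("models round-trip through the JSON checkpoint", {
  ds <- toy_dataset(n = 80)
  cfg <- train_config(epochs = 30, milestones = 20, batch_size = 64, seed = 2)
  model <- train_stiffness_model(ds, spec = mlp_spec(hidden = rep(6, 12)),
                                 config = cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  X <- tibble::as_tibble(ds)[1:11, ]
  expect_equal(predict_properties(back, X)$E_core,
               predict_properties(model, X)$E_core, tolerance = 1e-10)
  expect_equal(back$spec$layer_sizes, model$spec$layer_sizes)
})
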