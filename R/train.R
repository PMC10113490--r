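#' Training configuration
#'
#' Adam optimization of the mean squared error on z-scored inputs and
#' targets, with the milestone learning-rate schedule of the study:
#' 7000 epochs starting at 1e-3, decaying by a factor 10 at epochs
#' 500, 1000, 1500, 2000, 3500 and 5000. Data are split 80/10/10 into
#' training, internal validation and test.
#'
#' @param epochs Number of epochs.
#' @param lr Initial learning rate.
#' @param milestones Epochs at which the learning rate decays.
#' @param gamma Decay factor per milestone.
#' @param fractions Train/validation/test fractions (sum to 1).
#' @param batch_size Mini-batch size; `Inf` for full batch.
#' @param seed Seed for the split, initialization and shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 7000L, lr = 1e-3,
                         milestones = c(500, 1000, 1500, 2000, 3500, 5000),
                         gamma = 0.1, fractions = c(0.8, 0.1, 0.1),
                         batch_size = 256L, seed = 1L) {
  stopifnot(all(diff(milestones) > 0), gamma > 0, epochs >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 milestones = milestones, gamma = gamma,
                 fractions = fractions, batch_size = batch_size,
                 seed = as.integer(seed)),
            class = "train_config")
}

# apply a model's input transform to a feature table
atheromech_transform_inputs <- function(tbl, model) {
  transform_inputs(tbl, model$inputs, model$input_transform %||% "identity")
}

# log-transform the strictly positive input features (SR stays linear)
transform_inputs <- function(tbl, inputs, input_transform) {
  if (!identical(input_transform, "log")) return(tbl)
  out <- tbl
  for (v in setdiff(inputs, "SR")) {
    x <- out[[v]]
    if (any(x <= 0)) {
      ath_abort(paste0("input feature '", v, "' must be strictly positive for the log transform"),
                "atheromech_domain_error")
    }
    out[[v]] <- log(x)
  }
  out
}

lr_schedule <- function(config) {
  lr <- rep(config$lr, config$epochs)
  for (ms in config$milestones) {
    if (ms < config$epochs) lr[(ms + 1):config$epochs] <-
        lr[(ms + 1):config$epochs] * config$gamma
  }
  lr
}

#' Train the stiffness-prediction network
#'
#' End-to-end supervised training on a feature/target dataset: split
#' (80/10/10 by default), z-score scaling fitted on the training rows
#' only (inputs and targets), mini-batch Adam on the mean squared
#' error with the milestone learning-rate schedule, and per-epoch
#' train/validation loss recording. Deterministic for a fixed seed
#' and thread configuration.
#'
#' @param dataset A `dataset_table` (or data frame with the input
#'   columns and `E_core`, `E_plaque`).
#' @param inputs Character vector of input feature columns (default:
#'   the pinned network inputs, see [select_ann_inputs()]).
#' @param spec An [mlp_spec()]; input width must match `inputs`.
#' @param config A [train_config()].
#' @param target_transform `"log10"` (default) regresses the network
#'   on z-scored log moduli, `"identity"` on z-scored raw kPa. The
#'   moduli span two orders of magnitude on log-spaced grids and the
#'   accuracy metric of record is the relative error, which is
#'   additive on the log scale; a raw-kPa squared loss would weight
#'   an error at 1 kPa ten-thousand-fold less than the same relative
#'   error at 100 kPa. Predictions are always returned in kPa.
#' @param input_transform `"log"` (default) feeds the network the
#'   logarithms of the strictly positive input features (the squared
#'   strains) before z-scoring; `"identity"` scales them raw. The
#'   squared strains span two orders of magnitude with a heavy right
#'   skew, and the feature-to-modulus map is close to linear in
#'   log-log coordinates; the transform is monotone, so the pinned
#'   input set carries exactly the same information either way.
#' @param verbose Print the validation loss at each milestone.
#' @return An object of class `trained_model`: network parameters,
#'   input/output scalers, loss history (`epoch`, `lr`, `train_mse`,
#'   `val_mse`, z-scored target units), the split indices, and
#'   evaluation ranges.
#' @export
train_stiffness_model <- function(dataset,
                                  inputs = c("eps_core_sq", "eps_cap_sq",
                                             "eps_theta_sq", "SR"),
                                  spec = mlp_spec(n_in = length(inputs)),
                                  config = train_config(),
                                  target_transform = c("log10", "identity"),
                                  input_transform = c("log", "identity"),
                                  verbose = FALSE) {
  target_transform <- match.arg(target_transform)
  input_transform <- match.arg(input_transform)
  targets <- c("E_core", "E_plaque")
  data <- tibble::as_tibble(dataset)
  if ("status" %in% names(data)) data <- data[data$status == "ok", ]
  missing <- setdiff(c(inputs, targets), names(data))
  if (length(missing)) {
    ath_abort(paste0("dataset lacks column(s): ", paste(missing, collapse = ", ")),
              "atheromech_schema_error")
  }
  if (spec$layer_sizes[1] != length(inputs)) {
    ath_abort("network input width does not match the number of input features",
              "atheromech_shape_error")
  }

  split <- split_dataset(data, config$fractions, seed = config$seed)
  ytrans <- function(tbl) {
    out <- tbl
    if (target_transform == "log10") {
      for (t in targets) out[[t]] <- log10(out[[t]])
    }
    out
  }
  xtrans <- function(tbl)

    transform_inputs(tbl, inputs, input_transform)
  x_scaler <- zscore_fit(xtrans(split$train), inputs)
  y_scaler <- zscore_fit(ytrans(split$train), targets)
  as_xy <- function(tbl) {
    list(X = as.matrix(zscore_apply(x_scaler, xtrans(tbl)[, inputs, drop = FALSE])),
         Y = as.matrix(zscore_apply(y_scaler, ytrans(tbl)[, targets, drop = FALSE])))
  }
  tr <- as_xy(split$train)
  va <- as_xy(split$validation)

  fit <- train_mlp_matrices(tr$X, tr$Y, va$X, va$Y, spec, config,
                            verbose = verbose)

  structure(list(
    spec = spec, params = fit$params, config = config,
    inputs = inputs, targets = targets,
    target_transform = target_transform,
    input_transform = input_transform,
    x_scaler = x_scaler, y_scaler = y_scaler,
    history = fit$history,
    split_indices = attr(split, "indices"),
    input_ranges = lapply(split$train[, inputs, drop = FALSE], range),
    finetuned_layers = NULL
  ), class = "trained_model")
}

# Core training loop on scaled matrices. The numerical work runs in a
# compiled kernel (src/mlp_train.cpp) that mirrors the R reference
# implementation in mlp.R step for step; the R functions remain the
# documented reference and the cross-check used by the tests. Batch
# shuffling draws from R's RNG inside the kernel, so runs stay
# reproducible from the R-side seed.
train_mlp_matrices <- function(Xtr, Ytr, Xva = NULL, Yva = NULL, spec, config,
                               params = NULL, trainable = NULL,
                               verbose = FALSE) {
  set.seed(config$seed + 1L)
  params <- params %||% mlp_init(spec, seed = config$seed)
  lrs <- lr_schedule(config)
  m <- nrow(Xtr)
  bs <- if (is.finite(config$batch_size)) min(config$batch_size, m) else m
  if (is.null(trainable)) trainable <- rep(TRUE, length(params$W))
  if (is.null(Xva)) {
    Xva <- matrix(0, 0, ncol(Xtr))
    Yva <- matrix(0, 0, ncol(Ytr))
  }
  fit <- tryCatch(
    cpp_mlp_train(Xtr, Ytr, Xva, Yva, params$W, params$b,
                  lrs, as.integer(bs), trainable,
                  0.9, 0.999, 1e-8),
    error = function(e) {
      ath_abort(paste0("training diverged: ", conditionMessage(e)),
                "atheromech_training_error")
    })
  params$W <- fit$W
  params$b <- lapply(fit$b, as.numeric)
  hist_train <- as.numeric(fit$train_mse)
  hist_val <- as.numeric(fit$val_mse)
  if (verbose) {
    for (epoch in unique(pmin(c(config$milestones, config$epochs), config$epochs))) {
      message(sprintf("epoch %5d  lr %.1e  train %.3e  val %.3e",
                      epoch, lrs[epoch], hist_train[epoch], hist_val[epoch]))
    }
  }
  list(params = params,
       history = tibble::tibble(epoch = seq_len(config$epochs), lr = lrs,
                                train_mse = hist_train, val_mse = hist_val))
}

# Pure-R reference training loop (one-to-one with the compiled
# kernel); kept for the equivalence tests.
train_mlp_matrices_ref <- function(Xtr, Ytr, spec, config,
                                   params = NULL, trainable = NULL) {
  set.seed(config$seed + 1L)
  params <- params %||% mlp_init(spec, seed = config$seed)
  state <- adam_init(params)
  lrs <- lr_schedule(config)
  m <- nrow(Xtr)
  bs <- if (is.finite(config$batch_size)) min(config$batch_size, m) else m
  n_batch <- ceiling(m / bs)
  for (epoch in seq_len(config$epochs)) {
    perm <- if (n_batch > 1) sample.int(m) else seq_len(m)
    lr <- lrs[epoch]
    for (bidx in seq_len(n_batch)) {
      rows <- perm[((bidx - 1) * bs + 1):min(bidx * bs, m)]
      As <- mlp_forward_cached(params, Xtr[rows, , drop = FALSE])
      grads <- mlp_backward(params, As, Ytr[rows, , drop = FALSE], trainable)
      upd <- adam_step(params, grads, state, lr, trainable = trainable)
      params <- upd$params; state <- upd$state
    }
  }
  params
}

#' Evaluate a trained model
#'
#' Per-case relative errors \eqn{|\hat y - y|/y \cdot 100} of both
#' predicted moduli, computed in physical units (kPa) after inverse
#' scaling, with mean/median/max aggregates.
#'
#' @param model A `trained_model`.
#' @param data Data frame with the model's input columns and true
#'   `E_core`, `E_plaque`; rows with non-positive targets are
#'   excluded with a warning count.
#' @return An object of class `eval_report`: `cases` (per-case errors,
#'   percent) and `summary` (per-target aggregates).
#' @export
evaluate <- function(model, data) {
  stopifnot(inherits(model, "trained_model"))
  data <- tibble::as_tibble(data)
  if ("status" %in% names(data)) data <- data[data$status == "ok", ]
  bad <- data$E_core <= 0 | data$E_plaque <= 0
  if (any(bad)) {
    rlang::warn(sprintf("%d case(s) with non-positive targets excluded", sum(bad)))
    data <- data[!bad, ]
  }
  pred <- predict_properties(model, data)
  cases <- tibble::tibble(
    case_id = if ("case_id" %in% names(data)) data$case_id else
      as.character(seq_len(nrow(data))),
    E_core_true = data$E_core, E_core_pred = pred$E_core,
    E_plaque_true = data$E_plaque, E_plaque_pred = pred$E_plaque,
    err_E_core = abs(pred$E_core - data$E_core) / data$E_core * 100,
    err_E_plaque = abs(pred$E_plaque - data$E_plaque) / data$E_plaque * 100
  )
  summary <- tidyr::pivot_longer(cases, c("err_E_core", "err_E_plaque"),
                                 names_to = "target", values_to = "err") |>
    dplyr::mutate(target = sub("err_", "", .data$target)) |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(mean = mean(.data$err), median = stats::median(.data$err),
                     max = max(.data$err), n = dplyr::n(), .groups = "drop")
  structure(list(cases = cases, summary = summary), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", nrow(x$cases), "cases\n")
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' Predict moduli from deformation features
#'
#' Applies the trained network to new feature rows and returns
#' physical-unit predictions via inverse output scaling. Features more
#' than 3 times outside the training range are flagged.
#'
#' @param model A `trained_model`.
#' @param features Data frame with the model's input columns.
#' @return Tibble with `E_core`, `E_plaque` (kPa) and
#'   `out_of_range` flag, one row per input row, order preserved.
#' @export
predict_properties <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  features <- tibble::as_tibble(features)
  missing <- setdiff(model$inputs, names(features))
  if (length(missing)) {
    ath_abort(paste0("features lack column(s): ", paste(missing, collapse = ", ")),
              "atheromech_schema_error")
  }
  X <- as.matrix(zscore_apply(model$x_scaler,
                              transform_inputs(features, model$inputs,
                                               model$input_transform %||% "identity")[,
                                model$inputs, drop = FALSE]))
  oor <- rep(FALSE, nrow(X))
  for (v in model$inputs) {
    rg <- model$input_ranges[[v]]
    span <- diff(rg)
    lo <- rg[1] - 3 * span; hi <- rg[2] + 3 * span
    oor <- oor | features[[v]] < lo | features[[v]] > hi
  }
  if (any(oor)) {
    rlang::warn(sprintf("%d prediction(s) far outside the training feature range",
                        sum(oor)), class = "atheromech_extrapolation")
  }
  Ys <- mlp_forward(model$params, X)
  colnames(Ys) <- model$targets
  out <- zscore_invert(model$y_scaler, as.data.frame(Ys))
  if (identical(model$target_transform %||% "identity", "log10")) {
    for (t in model$targets) out[[t]] <- 10^out[[t]]
  }
  out$out_of_range <- oor
  tibble::as_tibble(out)
}

#' @export
print.trained_model <- function(x, ...) {
  sizes <- x$spec$layer_sizes
  cat("<trained_model>", paste(sizes, collapse = "-"),
      sprintf("(%d layers)\n", x$spec$n_layers))
  n <- nrow(x$history)
  cat(sprintf("  final train MSE %.3e, validation MSE %.3e (z-scored)\n",
              x$history$train_mse[n], x$history$val_mse[n]))
  if (!is.null(x$finetuned_layers)) {
    cat("  fine-tuned layers:", paste(x$finetuned_layers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trained_model <- function(x, ...) {
  L <- length(x$params$W)
  tibble::tibble(
    layer = seq_len(L),
    input_width = vapply(x$params$W, nrow, integer(1)),
    output_width = vapply(x$params$W, ncol, integer(1)),
    n_parameters = vapply(seq_len(L), function(l)
      length(x$params$W[[l]]) + length(x$params$b[[l]]), integer(1)),
    weight_norm = vapply(x$params$W, function(w) sqrt(mean(w^2)), numeric(1))
  )
}

#' @exportS3Method generics::glance
glance.trained_model <- function(x, ...) {
  n <- nrow(x$history)
  tibble::tibble(
    layers = x$spec$n_layers,
    parameters = sum(tidy(x)$n_parameters),
    epochs = n,
    train_mse = x$history$train_mse[n],
    val_mse = x$history$val_mse[n]
  )
}

#' Save and load trained models
#'
#' JSON container holding layer sizes, weights, scalers, training
#' configuration and seed.
#'
#' @param model A `trained_model`.
#' @param path File path (`.json`).
#' @return The model (read) or `path` invisibly (write).
#' @export
write_model <- function(model, path) {
  payload <- list(
    layer_sizes = model$spec$layer_sizes,
    W = lapply(model$params$W, function(w) as.data.frame(w)),
    b = model$params$b,
    inputs = model$inputs, targets = model$targets,
    target_transform = model$target_transform %||% "identity",
    input_transform = model$input_transform %||% "identity",
    x_scaler = unclass(model$x_scaler), y_scaler = unclass(model$y_scaler),
    config = unclass(model$config),
    input_ranges = model$input_ranges,
    finetuned_layers = model$finetuned_layers,
    history_tail = utils::tail(model$history, 1)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- p$layer_sizes
  spec <- mlp_spec(sizes[1], sizes[-c(1, length(sizes))], sizes[length(sizes)])
  W <- lapply(p$W, function(w) as.matrix(w))
  as_scaler <- function(s) structure(
    list(mu = setNames(as.numeric(s$mu), s$cols),
         sigma = setNames(as.numeric(s$sigma), s$cols),
         cols = s$cols), class = "zscaler")
  xs <- as_scaler(p$x_scaler)
  ys <- as_scaler(p$y_scaler)
  structure(list(
    spec = spec, params = list(W = W, b = p$b),
    config = p$config, inputs = p$inputs, targets = p$targets,
    target_transform = p$target_transform %||% "identity",
    input_transform = p$input_transform %||% "identity",
    x_scaler = xs, y_scaler = ys,
    history = tibble::as_tibble(p$history_tail),
    split_indices = NULL,
    input_ranges = p$input_ranges,
    finetuned_layers = p$finetuned_layers
  ), class = "trained_model")
}
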