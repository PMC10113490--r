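#' Fine-tuning configuration
#'
#' Domain adaptation by layer freezing: all but the last
#' `n_trainable` layers keep their weights fixed and only the network
#' tail is re-trained on (by default) a stratified half of the
#' realistic-family dataset; the other half is reserved for
#' evaluation. The fine-tuning defaults run Adam at the pre-training
#' starting rate (1e-3) for 8000 epochs: with only the four tail
#' layers trainable and about a thousand adaptation cases, each epoch
#' is a handful of cheap steps, and pilot runs showed the adaptation
#' still improving well past the gentle schedules that suffice for
#' full-network training.
#'
#' @param n_trainable Number of trainable tail layers (default 4).
#' @param train_fraction Fraction of the realistic data used for
#'   fine-tuning (default 0.5).
#' @param epochs,lr,batch_size Fine-tuning optimizer settings.
#' @param seed Seed for the stratified split and shuffling.
#' @return A list of class `finetune_config`.
#' @export
finetune_config <- function(n_trainable = 4L, train_fraction = 0.5,
                            epochs = 8000L, lr = 1e-3, batch_size = 256L,
                            seed = 1L) {
  stopifnot(n_trainable >= 0, train_fraction > 0, train_fraction < 1)
  structure(list(n_trainable = as.integer(n_trainable),
                 train_fraction = train_fraction,
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "finetune_config")
}

#' Stratified half-split of a realistic dataset
#'
#' Splits case rows into fine-tuning and evaluation halves, stratified
#' over cap thickness and the decade of the core modulus so both
#' halves span the full ranges (prevents degenerate extrapolation in
#' the held-out half).
#'
#' @param dataset A `dataset_table`.
#' @param train_fraction Fraction assigned to fine-tuning.
#' @param seed Seed.
#' @return List with `finetune` and `evaluation` tibbles; indices as
#'   attribute `indices`.
#' @export
split_realistic <- function(dataset, train_fraction = 0.5, seed = 1L) {
  data <- tibble::as_tibble(dataset)
  set.seed(seed)
  strata <- interaction(
    cut(data$cap_thk, breaks = unique(c(65, 100, 150, 220, 300)),
        include.lowest = TRUE),
    cut(log10(data$E_core), breaks = c(-Inf, 0.5, 1, 1.5, Inf)),
    drop = TRUE)
  idx_ft <- unlist(lapply(split(seq_len(nrow(data)), strata), function(ix)
    sample(ix, round(train_fraction * length(ix)))))
  idx_ft <- sort(idx_ft)
  idx_ev <- setdiff(seq_len(nrow(data)), idx_ft)
  out <- list(finetune = data[idx_ft, ], evaluation = data[idx_ev, ])
  attr(out, "indices") <- list(finetune = idx_ft, evaluation = idx_ev)
  out
}

#' Freeze-and-fine-tune a trained network
#'
#' Re-trains only the last `config$n_trainable` layers of a trained
#' model on the fine-tuning half of a realistic dataset; all other
#' weights are bit-identical before and after. The model's scalers
#' are reused unchanged (the network must keep operating in its
#' original feature space). With `n_trainable = 0` the model is
#' returned unchanged.
#'
#' @param model A `trained_model` (trained on idealized data).
#' @param realistic A `dataset_table` sharing the model's feature
#'   schema (only the fine-tuning rows are used; pass the output of
#'   [split_realistic()]`$finetune` or a full table, see
#'   `presplit`).
#' @param config A [finetune_config()].
#' @param presplit If `TRUE` (default) `realistic` is split
#'   internally with [split_realistic()]; if `FALSE`, all rows are
#'   used for fine-tuning.
#' @return A list of class `finetune_result`: `model` (fine-tuned),
#'   `history`, and (when `presplit`) the held-out `evaluation`
#'   tibble and split indices.
#' @export
freeze_and_finetune <- function(model, realistic, config = finetune_config(),
                                presplit = TRUE) {
  stopifnot(inherits(model, "trained_model"))
  data <- tibble::as_tibble(realistic)
  if ("status" %in% names(data)) data <- data[data$status == "ok", ]
  missing <- setdiff(c(model$inputs, model$targets), names(data))
  if (length(missing)) {
    ath_abort(paste0("realistic data lacks column(s): ",
                     paste(missing, collapse = ", ")), "atheromech_schema_error")
  }
  if (presplit) {
    halves <- split_realistic(data, config$train_fraction, seed = config$seed)
    ft <- halves$finetune
  } else {
    halves <- NULL
    ft <- data
  }
  L <- length(model$params$W)
  if (config$n_trainable > L) {
    ath_abort("more trainable layers requested than the network has",
              "atheromech_domain_error")
  }
  trainable <- rep(FALSE, L)
  if (config$n_trainable > 0) {
    trainable[(L - config$n_trainable + 1):L] <- TRUE
  }

  X <- as.matrix(zscore_apply(model$x_scaler,
    atheromech_transform_inputs(ft, model)[, model$inputs, drop = FALSE]))
  ytbl <- ft[, model$targets, drop = FALSE]
  if (identical(model$target_transform %||% "identity", "log10")) {
    for (t in model$targets) ytbl[[t]] <- log10(ytbl[[t]])
  }
  Y <- as.matrix(zscore_apply(model$y_scaler, ytbl))

  if (config$n_trainable == 0) {
    tuned <- model
    history <- tibble::tibble(epoch = integer(), lr = double(),
                              train_mse = double(), val_mse = double())
  } else {
    tc <- train_config(epochs = config$epochs, lr = config$lr,
                       milestones = config$epochs, gamma = 1,
                       batch_size = config$batch_size, seed = config$seed)
    fit <- train_mlp_matrices(X, Y, NULL, NULL, model$spec, tc,
                              params = model$params, trainable = trainable)
    tuned <- model
    tuned$params <- fit$params
    tuned$history <- fit$history
    tuned$finetuned_layers <- which(trainable)
    history <- fit$history
  }

  structure(list(model = tuned, history = history,
                 evaluation = if (presplit) halves$evaluation else NULL,
                 indices = if (presplit) attr(halves, "indices") else NULL,
                 config = config),
            class = "finetune_result")
}

#' Three-case evaluation of idealized training and transfer
#'
#' Reproduces the study's evaluation protocol:
#' \enumerate{
#' \item the idealized-trained network on its own train and test
#'   splits;
#' \item the same network, unadapted, on the held-out half of the
#'   realistic dataset (domain shift);
#' \item the fine-tuned network on that same held-out half.
#' }
#' Also reports the qualitative ordering check (case-2 error much
#' larger than case-3).
#'
#' @param model A `trained_model` trained on the idealized dataset.
#' @param idealized The idealized `dataset_table` it was trained on.
#' @param realistic A realistic-family `dataset_table`.
#' @param config A [finetune_config()].
#' @return An object of class `case_study_report`: `case1_train`,
#'   `case1_test`, `case2`, `case3` (eval reports), the fine-tuned
#'   model, and a `summary` tibble.
#' @export
run_case_study <- function(model, idealized, realistic,
                           config = finetune_config()) {
  stopifnot(inherits(model, "trained_model"))
  data <- tibble::as_tibble(idealized)
  if ("status" %in% names(data)) data <- data[data$status == "ok", ]
  idx <- model$split_indices
  if (is.null(idx)) {
    # model restored from disk without its split bookkeeping: report
    # case 1 over the full idealized table
    idx <- list(train = seq_len(nrow(data)), test = seq_len(nrow(data)))
  }
  case1_train <- evaluate(model, data[idx$train, ])
  case1_test <- evaluate(model, data[idx$test, ])

  ft <- freeze_and_finetune(model, realistic, config)
  case2 <- evaluate(model, ft$evaluation)
  case3 <- evaluate(ft$model, ft$evaluation)

  pick <- function(rep, t) {
    unname(rep$summary$mean[rep$summary$target == t])
  }
  summary <- tibble::tibble(
    case = c("case1_train", "case1_test", "case2_realistic", "case3_finetuned"),
    err_E_core = c(pick(case1_train, "E_core"), pick(case1_test, "E_core"),
                   pick(case2, "E_core"), pick(case3, "E_core")),
    err_E_plaque = c(pick(case1_train, "E_plaque"), pick(case1_test, "E_plaque"),
                     pick(case2, "E_plaque"), pick(case3, "E_plaque"))
  )
  structure(list(case1_train = case1_train, case1_test = case1_test,
                 case2 = case2, case3 = case3,
                 finetuned = ft$model, summary = summary,
                 ordering_ok = all(summary[summary$case == "case2_realistic", -1] >
                                     5 * summary[summary$case == "case3_finetuned", -1])),
            class = "case_study_report")
}

#' @export
print.case_study_report <- function(x, ...) {
  cat("<case_study_report> mean relative errors (%)\n")
  print(as.data.frame(x$summary), digits = 3)
  cat("case-2 error exceeds 5x case-3:", x$ordering_ok, "\n")
  invisible(x)
}

#' Serialize a case-study report to JSON
#'
#' @param report A `case_study_report`.
#' @param path File path.
#' @return `path` invisibly; `read_case_study()` restores the summary
#'   and per-case aggregates (not the per-case tables).
#' @export
write_case_study <- function(report, path) {
  payload <- list(
    summary = report$summary,
    ordering_ok = report$ordering_ok,
    aggregates = lapply(report[c("case1_train", "case1_test", "case2", "case3")],
                        function(r) r$summary)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_case_study
#' @export
read_case_study <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$summary <- tibble::as_tibble(p$summary)
  p
}
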