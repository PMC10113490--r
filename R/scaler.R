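#' z-score scaling
#'
#' Per-column standardization \eqn{x_{scaled} = (x - \mu)/\sigma},
#' with the statistics fitted on training rows only so no information
#' leaks from validation or test data.
#'
#' @param data Data frame or matrix of numeric columns.
#' @param cols Columns to scale (default: all numeric columns).
#' @return `zscore_fit()` returns a `zscaler`; `zscore_apply()` and
#'   `zscore_invert()` return the transformed table with the same
#'   shape and column names.
#' @export
zscore_fit <- function(data, cols = NULL) {
  data <- as.data.frame(data)
  cols <- cols %||% names(data)[vapply(data, is.numeric, logical(1))]
  mu <- vapply(cols, function(cl) mean(data[[cl]]), numeric(1))
  sigma <- vapply(cols, function(cl) sd(data[[cl]]), numeric(1))
  if (any(sigma == 0 | !is.finite(sigma))) {
    bad <- cols[sigma == 0 | !is.finite(sigma)]
    ath_abort(paste0("zero-variance column(s): ", paste(bad, collapse = ", ")),
              "atheromech_domain_error")
  }
  structure(list(mu = mu, sigma = sigma, cols = cols), class = "zscaler")
}

#' @rdname zscore_fit
#' @param scaler A `zscaler`.
#' @export
zscore_apply <- function(scaler, data) {
  stopifnot(inherits(scaler, "zscaler"))
  out <- as.data.frame(data)
  for (cl in scaler$cols) out[[cl]] <- (out[[cl]] - scaler$mu[[cl]]) / scaler$sigma[[cl]]
  tibble::as_tibble(out)
}

#' @rdname zscore_fit
#' @export
zscore_invert <- function(scaler, data) {
  stopifnot(inherits(scaler, "zscaler"))
  out <- as.data.frame(data)
  for (cl in scaler$cols) out[[cl]] <- out[[cl]] * scaler$sigma[[cl]] + scaler$mu[[cl]]
  tibble::as_tibble(out)
}

#' Random train/validation/test split
#'
#' Disjoint, exhaustive, uniformly random partition under a seed.
#'
#' @param data Data frame.
#' @param fractions Positive fractions summing to 1 (default 80/10/10).
#' @param seed Integer seed.
#' @return Named list `train`, `validation`, `test` of tibbles; row
#'   indices attached as attribute `indices`.
#' @export
split_dataset <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) {
    ath_abort("split fractions must sum to 1", "atheromech_domain_error")
  }
  n <- nrow(data)
  if (n < 10) ath_abort("need at least 10 rows to split", "atheromech_domain_error")
  set.seed(seed)
  perm <- sample.int(n)
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  idx <- list(train = perm[seq_len(n_tr)],
              validation = perm[n_tr + seq_len(n_va)],
              test = perm[(n_tr + n_va + 1):n])
  out <- lapply(idx, function(i) tibble::as_tibble(data[i, , drop = FALSE]))
  attr(out, "indices") <- idx
  out
}
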