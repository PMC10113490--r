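#' Ordinary least squares with tidy output
#'
#' Thin wrapper around [stats::lm()] returning the quantities used in
#' the feature-selection workflow: coefficients, two-sided t-test
#' p-values, adjusted R-squared (in percent) and per-predictor
#' variance inflation factors.
#'
#' @param data Data frame containing predictors and response.
#' @param response Name of the response column (string).
#' @param predictors Character vector of predictor columns.
#' @return An object of class `ath_ols` wrapping the `lm` fit;
#'   [tidy()] and [glance()] methods give coefficient and model-level
#'   summaries.
#' @export
ols_fit <- function(data, response, predictors) {
  stopifnot(is.character(response), length(response) == 1,
            is.character(predictors))
  if (nrow(data) < length(predictors) + 2) {
    ath_abort("need at least p + 2 rows to fit p predictors", "atheromech_domain_error")
  }
  sds <- vapply(predictors, function(p) sd(data[[p]]), numeric(1))
  if (any(sds == 0)) {
    ath_abort(paste0("zero-variance predictor(s): ",
                     paste(predictors[sds == 0], collapse = ", ")),
              "atheromech_domain_error")
  }
  fml <- stats::reformulate(predictors, response)
  fit <- lm(fml, data = data)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    ath_abort(paste0("rank-deficient design; dependent column(s): ",
                     paste(bad, collapse = ", ")), "atheromech_singular_error")
  }
  structure(list(fit = fit, response = response, predictors = predictors,
                 vif = if (length(predictors) >= 2) vif(data[predictors]) else
                   setNames(rep(NA_real_, length(predictors)), predictors)),
            class = "ath_ols")
}

#' @exportS3Method generics::tidy
tidy.ath_ols <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"]),
    vif = unname(c(NA_real_, x$vif[rownames(sm)[-1]]))
  )
}

#' @exportS3Method generics::glance
glance.ath_ols <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    r_squared = sm$r.squared * 100,
    adj_r_squared = sm$adj.r.squared * 100,
    sigma = sm$sigma,
    n = length(sm$residuals),
    p = length(x$predictors)
  )
}

#' @export
print.ath_ols <- function(x, ...) {
  cat("<ath_ols>", x$response, "~", paste(x$predictors, collapse = " + "), "\n")
  print(tidy(x), n = Inf)
  cat(sprintf("adjusted R^2 = %.2f%%\n", glance(x)$adj_r_squared))
  invisible(x)
}

#' Adjusted R-squared
#'
#' \deqn{R^2_{adj} = 1 - (1 - R^2)\frac{n - 1}{n - p - 1},}
#' reported in percent.
#'
#' @param R2 Coefficient of determination as a fraction in `[0, 1]`.
#' @param n Number of observations.
#' @param p Number of predictors (excluding the intercept).
#' @return Adjusted R-squared in percent.
#' @examples
#' adjusted_R2(0.9, 100, 2)
#' @export
adjusted_R2 <- function(R2, n, p) {
  if (any(n <= p + 1)) {
    ath_abort("adjusted R^2 requires n > p + 1", "atheromech_domain_error")
  }
  (1 - (1 - R2) * (n - 1) / (n - p - 1)) * 100
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1/(1 - R_j^2)} where \eqn{R_j^2} is from regressing
#' predictor j on the remaining predictors. Exactly collinear columns
#' are reported as infinite.
#'
#' @param X Data frame (or matrix) of at least two predictors.
#' @return Named numeric vector of VIFs.
#' @examples
#' vif(data.frame(a = rnorm(50), b = rnorm(50)))
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) ath_abort("VIF needs at least two predictors", "atheromech_domain_error")
  out <- vapply(seq_along(X), function(j) {
    fit <- lm(stats::reformulate(names(X)[-j], names(X)[j]), data = X)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, names(X))
}

#' Bidirectional p-value stepwise selection with a VIF audit
#'
#' Mirrors the study's selection procedure: starting from an empty
#' model, the most significant candidate enters while it clears the
#' entry test, any included predictor that no longer clears the stay
#' test leaves, and after the stepwise phase a multicollinearity
#' audit repeatedly drops one member of the worst collinear pair --
#' the member whose removal leaves the higher adjusted R-squared --
#' until all VIFs are at most `vif_cap`. With two responses
#' (multivariate mode) the procedure runs per response and the final
#' selection is the set significant for both.
#'
#' The entry/stay threshold applies `alpha` family-wise over the
#' candidate pool (Bonferroni: each test at `alpha/m` for `m`
#' candidates, the default). Without that control, screening `m`
#' null candidates at a raw 0.05 admits a spurious predictor in about
#' `1 - 0.95^m` of datasets — selection would be anti-conservative in
#' exactly the way the procedure is meant to prevent. Every selected
#' predictor still satisfies `p < alpha` (indeed `p < alpha/m`) in
#' the final model. Set `family_wise = FALSE` for raw per-test
#' thresholds.
#'
#' @param data Data frame with candidates and response(s).
#' @param responses One or two response column names.
#' @param candidates Candidate predictor column names.
#' @param alpha Family-wise entry/stay significance level (default 0.05).
#' @param vif_cap VIF audit threshold (default 10).
#' @param family_wise Apply the Bonferroni pool correction (default
#'   `TRUE`).
#' @return An object of class `ath_selection`: `selected` (character),
#'   per-step `log` tibble, and the final refitted model(s).
#' @export
stepwise_select <- function(data, responses, candidates, alpha = 0.05,
                            vif_cap = 10, family_wise = TRUE) {
  stopifnot(length(candidates) >= 1, length(responses) %in% 1:2)
  alpha_step <- if (family_wise) alpha / length(candidates) else alpha
  runs <- lapply(responses, function(resp)
    stepwise_single(data, resp, candidates, alpha_step, vif_cap))
  names(runs) <- responses

  selected <- if (length(responses) == 1) runs[[1]]$selected
  else intersect(runs[[1]]$selected, runs[[2]]$selected)

  models <- lapply(responses, function(resp) {
    if (length(selected) == 0) NULL
    else ols_fit(data, resp, selected)
  })
  names(models) <- responses

  structure(list(
    selected = selected,
    candidates = candidates,
    responses = responses,
    log = dplyr::bind_rows(lapply(names(runs), function(r)
      dplyr::mutate(runs[[r]]$log, response = r, .before = 1))),
    models = models,
    per_response = lapply(runs, `[[`, "selected"),
    alpha = alpha, vif_cap = vif_cap
  ), class = "ath_selection")
}

stepwise_single <- function(data, response, candidates, alpha, vif_cap) {
  included <- character(0)
  log <- list()
  note <- function(action, var, p = NA_real_, vifv = NA_real_) {
    log[[length(log) + 1]] <<- tibble::tibble(
      action = action, variable = var, p_value = p, vif = vifv)
  }
  p_of <- function(vars, target) {
    fit <- lm(stats::reformulate(vars, response), data = data)
    sm <- summary(fit)$coefficients
    if (!target %in% rownames(sm)) return(NA_real_)
    sm[target, "Pr(>|t|)"]
  }
  repeat {
    changed <- FALSE
    # entry: most significant excluded candidate
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      pvals <- vapply(pool, function(v) p_of(c(included, v), v), numeric(1))
      pvals[is.na(pvals)] <- Inf
      if (min(pvals) < alpha) {
        v <- pool[which.min(pvals)]
        included <- c(included, v)
        note("enter", v, p = min(pvals))
        changed <- TRUE
      }
    }
    # removal: any included predictor no longer significant
    if (length(included) > 1 || (length(included) == 1 && !changed)) {
      fit <- lm(stats::reformulate(included, response), data = data)
      sm <- summary(fit)$coefficients
      pv <- sm[intersect(rownames(sm), included), "Pr(>|t|)", drop = TRUE]
      if (length(pv) && max(pv) >= alpha) {
        v <- names(which.max(pv))
        included <- setdiff(included, v)
        note("remove", v, p = max(pv))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # VIF audit
  while (length(included) >= 2) {
    vifs <- vif(data[included])
    if (max(vifs) <= vif_cap) break
    worst <- names(which.max(vifs))
    # its strongest partner
    cors <- abs(stats::cor(data[[worst]],
                           data[setdiff(included, worst)]))[1, ]
    partner <- setdiff(included, worst)[which.max(cors)]
    adj_without <- function(v) {
      rest <- setdiff(included, v)
      if (!length(rest)) return(-Inf)
      glance(ols_fit(data, response, rest))$adj_r_squared
    }
    drop <- if (adj_without(worst) >= adj_without(partner)) worst else partner
    included <- setdiff(included, drop)
    note("vif_drop", drop, vifv = max(vifs))
  }
  log_tbl <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(action = character(), variable = character(),
                   p_value = double(), vif = double())
  list(selected = included, log = log_tbl)
}

#' @export
print.ath_selection <- function(x, ...) {
  cat("<ath_selection>", paste(x$responses, collapse = " & "), "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n")
  cat("  steps:", nrow(x$log), "\n")
  invisible(x)
}

#' Descriptive feature-target associations
#'
#' Per-feature Pearson and Spearman correlations against both moduli —
#' the descriptive half of the selection workflow, useful for spotting
#' the monotone-but-nonlinear trends that motivate the squared
#' features.
#'
#' @param dataset A `dataset_table`.
#' @return A tibble with one row per (feature, target) pair.
#' @export
describe_features <- function(dataset) {
  ok <- tibble::as_tibble(dataset)
  if ("status" %in% names(ok)) ok <- ok[ok$status == "ok", ]
  feats <- intersect(c("eps1", "eps2", "eps_core", "eps_cap", "eps_theta",
                       "eps_core_sq", "eps_cap_sq", "eps_theta_sq", "SR"),
                     names(ok))
  tidyr::expand_grid(feature = feats, target = c("E_core", "E_plaque")) |>
    dplyr::mutate(
      pearson = purrr::map2_dbl(.data$feature, .data$target, function(f, t)
        stats::cor(ok[[f]], ok[[t]])),
      spearman = purrr::map2_dbl(.data$feature, .data$target, function(f, t)
        stats::cor(ok[[f]], ok[[t]], method = "spearman")))
}

#' Network input selection for the stiffness predictor
#'
#' Runs the descriptive/inferential selection workflow on the nine
#' candidate features (principal strains, the three relative-change
#' features, their squares, and the stenosis ratio) against both
#' moduli, and returns the pinned input set used downstream --
#' squared core-, cap- and lumen-change features plus the stenosis
#' ratio -- together with the data-driven selection log for
#' comparison. The pinned set keeps downstream models stable across
#' re-simulated databases; the selection machinery documents how the
#' data-driven choice compares on the current dataset.
#'
#' @param dataset A `dataset_table`.
#' @param alpha,vif_cap Passed to [stepwise_select()].
#' @return A list of class `ann_input_selection`: `inputs` (ordered
#'   character vector of length 4) and `selection` (the
#'   `ath_selection` audit trail).
#' @export
select_ann_inputs <- function(dataset, alpha = 0.05, vif_cap = 10) {
  candidates <- c("eps1", "eps2", "eps_core", "eps_cap", "eps_theta",
                  "eps_core_sq", "eps_cap_sq", "eps_theta_sq", "SR")
  ok <- dataset[dataset$status == "ok", ]
  sel <- stepwise_select(as.data.frame(ok), c("E_core", "E_plaque"),
                         candidates, alpha = alpha, vif_cap = vif_cap)
  structure(list(
    inputs = c("eps_core_sq", "eps_cap_sq", "eps_theta_sq", "SR"),
    selection = sel
  ), class = "ann_input_selection")
}

#' @export
print.ann_input_selection <- function(x, ...) {
  cat("<ann_input_selection> pinned inputs:", paste(x$inputs, collapse = ", "), "\n")
  cat("  data-driven selection:", paste(x$selection$selected, collapse = ", "), "\n")
  invisible(x)
}
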