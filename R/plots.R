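#' Plot a plaque cross-section
#'
#' Region boundary contours, equal-axis, colored by region.
#'
#' @param object A `plaque_geometry`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.plaque_geometry <- function(object, ...) {
  lv <- c("adventitia", "media", "intima", "core", "lumen")
  df <- dplyr::mutate(object$contours,
                      region = factor(.data$region, levels = lv))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$region,
                                   colour = .data$region)) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("SR %.1f%%, cap %.0f um",
                                  object$SR, mm_to_um(object$shape$cap))) +
    ggplot2::theme_minimal()
}

#' Plot training curves
#'
#' Train and validation mean squared error (z-scored targets) per
#' epoch on a log scale, with the learning-rate milestones marked.
#'
#' @param object A `trained_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.trained_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_mse", "val_mse"),
                           names_to = "set", values_to = "mse") |>
    dplyr::filter(is.finite(.data$mse))
  ms <- object$config$milestones
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$mse, colour = .data$set)) +
    ggplot2::geom_line(alpha = 0.9) +
    ggplot2::geom_vline(xintercept = ms, linetype = 3, colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE (z-scored targets)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Distribution of per-case relative errors for both predicted
#' moduli.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$cases, c("err_E_core", "err_E_plaque"),
                              names_to = "target", values_to = "err") |>
    dplyr::mutate(target = sub("err_", "", .data$target))
  ggplot2::ggplot(long, ggplot2::aes(.data$target, .data$err,
                                     fill = .data$target)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "relative error (%)") +
    ggplot2::theme_minimal()
}

#' Plot a three-case study summary
#'
#' Mean relative error of both moduli for the idealized test, the
#' unadapted realistic evaluation, and the fine-tuned realistic
#' evaluation.
#'
#' @param object A `case_study_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.case_study_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary, c("err_E_core", "err_E_plaque"),
                              names_to = "target", values_to = "err") |>
    dplyr::mutate(target = sub("err_", "", .data$target))
  ggplot2::ggplot(long, ggplot2::aes(.data$case, .data$err, fill = .data$target)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "mean relative error (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Plot an inflation solution
#'
#' Lumen diameter versus applied pressure across the increments.
#'
#' @param object A `fem_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fem_solution <- function(object, ...) {
  df <- tibble::tibble(pressure = object$pressures,
                       diameter = object$lumen_diameter)
  ggplot2::ggplot(df, ggplot2::aes(.data$pressure, .data$diameter)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "pressure (kPa)", y = "lumen diameter (mm)") +
    ggplot2::theme_minimal()
}
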