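#' Plot a single-variable discretization
#'
#' Rug-style strip of the training class counts by value position with the
#' learned cut points as vertical dashed lines. Useful for eyeballing
#' whether cuts land between class-homogeneous runs.
#'
#' @param object A `discretization` object fitted by [ebd_discretize()] or
#'   [fi_discretize()] (needs `interval_counts`; deserialized models
#'   without counts plot cuts only).
#' @param data Optional data frame with the original `value` and `class`
#'   columns to show instead of interval summaries.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.discretization <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_jitter(
      data = data,
      ggplot2::aes(x = .data$value, y = .data$class, colour = .data$class),
      height = 0.1, width = 0, alpha = 0.8
    ) + ggplot2::labs(x = "predictor value", y = "class")
  } else if (!is.null(object$interval_counts)) {
    td <- tidy(object) |>
      tidyr::pivot_longer(dplyr::starts_with("n_"),
                          names_to = "class", values_to = "count",
                          names_prefix = "n_") |>
      dplyr::mutate(interval = factor(.data$interval))
    p <- p + ggplot2::geom_col(
      data = td,
      ggplot2::aes(x = .data$interval, y = .data$count, fill = .data$class),
      position = "dodge"
    ) + ggplot2::labs(x = "interval code", y = "training count")
  }
  if (object$n_intervals > 1L && !is.null(data)) {
    p <- p + ggplot2::geom_vline(xintercept = object$cut_values,
                                 linetype = "dashed")
  }
  p + ggplot2::ggtitle(sprintf("%s discretization, %d interval(s)",
                               object$method, object$n_intervals))
}

#' Plot the interval-count profile of a fitted discretization set
#'
#' Bar chart of how many predictors received each interval count `W`;
#' trivially discretized predictors (`W = 1`) are the filtered-out ones.
#'
#' @param object A `discretization_set` from [discretize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.discretization_set <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::count(.data$n_intervals)
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$n_intervals),
                                   y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "intervals per predictor", y = "predictors",
                  title = sprintf("%s: interval-count profile", object$method))
}

#' Plot per-fold evaluation measures of a cross-validation report
#'
#' Boxplots of test accuracy, test AUC and robustness over the
#' `reps x folds` train/test pairs.
#'
#' @param object A `cv_report` from [run_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::select(dplyr::all_of(c("replicate", "fold", "test_accuracy",
                                  "test_auc", "robustness"))) |>
    tidyr::pivot_longer(-c("replicate", "fold"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$measure, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~ .data$measure, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s: per-fold evaluation measures",
                                  object$method))
}
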