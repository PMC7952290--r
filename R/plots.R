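#' Plot methods for evaluation and comparison objects
#'
#' `autoplot.mapping_evaluation()` draws the calibration panel: observed
#' utilities grouped into quartiles on the x-axis (at the quartile mean),
#' with the median, interquartile range (thick bar) and 10th--90th centile
#' range (thin bar) of the predictions on the y-axis, against the identity
#' line. `autoplot.mapping_comparison()` dot-plots RMSE and MAE by model.
#' `plot_observed_predicted()` is the companion scatter of observed versus
#' predicted utilities.
#'
#' @param object an evaluation or comparison object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mapping_evaluation
#' @export
autoplot.mapping_evaluation <- function(object, ...) {
  q <- object$quartiles
  ggplot2::ggplot(q, ggplot2::aes(x = .data$mean_observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q10_predicted,
                                         ymax = .data$q90_predicted),
                            linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q25_predicted,
                                         ymax = .data$q75_predicted),
                            linewidth = 1.4, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_predicted), size = 2) +
    ggplot2::labs(x = "Observed utility (quartile mean)",
                  y = "Predicted utility",
                  title = "Calibration by observed-utility quartile") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mapping_evaluation
#' @method autoplot mapping_comparison
#' @export
autoplot.mapping_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("rmse", "mae"),
                              names_to = "metric", values_to = "value")
  long$model <- factor(long$model, levels = rev(unique(object$model)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$model)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, title = "Mapping algorithm comparison") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mapping_evaluation
#' @param predicted,observed numeric utility vectors.
#' @export
plot_observed_predicted <- function(predicted, observed) {
  df <- tibble::tibble(observed = observed, predicted = predicted)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::labs(x = "Observed utility", y = "Predicted utility") +
    ggplot2::theme_minimal()
}
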