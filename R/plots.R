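#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a single prognosis distribution
#'
#' Column plot of the softmax probability over the horizon months, the
#' model's probability that death occurs in each future month; the argmax
#' is the predicted life expectancy.
#'
#' @param probabilities Numeric probability vector (one row of
#'   `predict(model, windows, type = "prob")`).
#' @return A ggplot.
#' @export
plot_prognosis <- function(probabilities) {
  df <- tibble(month = seq_along(probabilities),
               probability = as.numeric(probabilities))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "months to death", y = "probability",
                  title = "Prognosis distribution") +
    ggplot2::theme_minimal()
}

#' Training-loss curve of a fitted LSTM
#'
#' @param object An `lstm_model`.
#' @param ... Unused.
#' @return A ggplot of per-epoch mean cross-entropy.
#' @export
autoplot.lstm_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$mean_loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy loss") +
    ggplot2::theme_minimal()
}

#' Actual vs predicted life-expectancy histogram
#'
#' Absolute frequency counts of actual and predicted life expectancies per
#' month over the horizon; with pooled sliding windows the actual counts
#' are flat at the test-cohort size.
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$histogram, c("actual_n", "predicted_n"),
                            names_to = "series", values_to = "count")
  df$series <- ifelse(df$series == "actual_n", "actual", "predicted")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$count,
                                   fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "months to death", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Certainty as a function of predicted life expectancy
#'
#' @param outcomes Outcome tibble from [prognosis_outcomes()].
#' @return A ggplot of mean certainty per predicted month.
#' @export
plot_certainty <- function(outcomes) {
  df <- outcomes |>
    dplyr::group_by(.data$predicted) |>
    dplyr::summarise(certainty = mean(.data$certainty), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$certainty)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "predicted months to death", y = "mean certainty") +
    ggplot2::theme_minimal()
}
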