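# ggplot2 display methods for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve plot
#'
#' @param object a `retino_roc`.
#' @param threshold optional operating threshold; its point is highlighted.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.retino_roc <- function(object, threshold = NULL, ...) {
  cv <- object$curve |> arrange(.data$sensitivity)
  p <- ggplot2::ggplot(cv, ggplot2::aes(x = 1 - .data$specificity,
                                        y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AUC = %.2f)", object$auc)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    i <- which.min(abs(cv$threshold - threshold))
    p <- p + ggplot2::geom_point(data = cv[i, ], colour = "darkgreen",
                                 size = 3)
  }
  p
}

#' Predicted-risk distribution by retinopathy grade at the prediction visit
#'
#' Boxplots of the predicted one-year STDR probability for patients showing
#' R0/R0, R0/R1 and R1/R1 at the prediction visit, optionally split by
#' outcome.
#'
#' @param object a `retino_scores` tibble.
#' @param by_label facet by the true outcome.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.retino_scores <- function(object, by_label = FALSE, ...) {
  d <- filter(object, !is.na(.data$prob_stdr))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pred_grade,
                                       y = .data$prob_stdr)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "Grades at prediction visit",
                  y = "Predicted 1-year STDR probability") +
    ggplot2::theme_minimal()
  if (by_label)
    p <- p + ggplot2::facet_wrap(~label,
                                 labeller = ggplot2::as_labeller(
                                   c(`TRUE` = "developed STDR",
                                     `FALSE` = "no STDR")))
  p
}

#' Method-comparison bar chart
#'
#' Sensitivity, specificity, PCC and screening reduction of the multivariate
#' discriminant versus each stratification rule.
#'
#' @param comparison output of [compare_methods()].
#' @return a ggplot.
#' @export
plot_method_comparison <- function(comparison) {
  long <- comparison |>
    select("method", "sensitivity", "specificity", "pcc",
           "screening_reduction") |>
    tidyr::pivot_longer(-"method", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Percent") +
    ggplot2::theme_minimal()
}
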