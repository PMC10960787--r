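#' Plot per-category evaluation metrics
#'
#' Bar chart of accuracy, sensitivity, specificity and precision per item
#' category (drug dose, drug-drug interaction, potassium warnings).
#'
#' @param object A `metric_report` from [evaluate_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- object$per_category |>
    tidyr::pivot_longer(
      cols = c("accuracy", "sensitivity", "specificity", "precision"),
      names_to = "metric", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion",
                  title = "Evaluation metrics by item category") +
    ggplot2::theme_minimal()
}

#' Plot the running mean squared error over patients
#'
#' @param object A `metric_report` from [evaluate_cohort()].
#' @return A ggplot object.
#' @export
plot_mse_curve <- function(object) {
  ggplot2::ggplot(object$mse_curve,
                  ggplot2::aes(x = .data$n_patients, y = .data$running_mse)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "patients evaluated", y = "running MSE",
                  title = "Mean squared error as patients accumulate") +
    ggplot2::theme_minimal()
}

#' Plot the CKD stage distribution of a cohort
#'
#' @param cohort Tibble of patients with a `gfr` column.
#' @param kb A `renal_kb` object.
#' @return A ggplot object.
#' @export
plot_stage_distribution <- function(cohort, kb = load_knowledge_base()) {
  df <- tibble(stage = factor(classify_ckd_stage(cohort$gfr, kb),
                              levels = .stage_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "CKD stage", y = "patients",
                  title = "Cohort CKD stage distribution") +
    ggplot2::theme_minimal()
}
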