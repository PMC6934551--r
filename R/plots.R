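#' Plot a fitted discount function against observed choices
#'
#' Draws the fitted value-discounting curve (discount fraction SV/A as a
#' function of delay) for the subject's MLE, overlaid with the observed
#' proportion of larger-later choices at each late delay — a quick visual
#' check that the fitted steepness tracks behaviour.
#'
#' @param object A `dd_fit` for a value-model family (not `"random"`).
#' @param records The choice records the model was fitted to.
#' @param max_delay Right edge of the delay axis in days.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dd_fit <- function(object, records, max_delay = 72, ...) {
  if (object$model == "random") {
    stop("the random baseline has no discount curve", call. = FALSE)
  }
  grid <- tibble::tibble(delay = seq(0, max_delay, length.out = 200))
  grid$fraction <- subjective_value(object$model, 1, grid$delay,
                                    object$params)
  obs <- valid_records(records) |>
    dplyr::group_by(delay = .data$late_delay_days) |>
    dplyr::summarise(p_ll = mean(.data$choice == "LL"), .groups = "drop")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$delay, y = .data$fraction)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(y = .data$p_ll), colour = "#b2182b") +
    ggplot2::labs(
      x = "delay (days)",
      y = "discount fraction / P(larger-later)",
      title = sprintf("%s fit, subject %s", object$model, object$subject_id)
    ) +
    ggplot2::theme_minimal()
}

#' Plot cohort model comparison
#'
#' Mean BIC per model with +-1 SD error bars; lower is better.
#'
#' @param comparison Output of [compare_models()].
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = stats::reorder(.data$model, .data$mean_bic),
                               y = .data$mean_bic)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_bic - .data$sd_bic,
                                        ymax = .data$mean_bic + .data$sd_bic),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean BIC (+-1 SD)") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Scatter plot of one association with influence flags
#'
#' Raw-scale scatter of an outcome against a predictor with the least-squares
#' line; points flagged influential by [outlier_diagnostics()] are marked.
#'
#' @param data Subject table.
#' @param predictor,outcome Column names (strings).
#' @return A ggplot object.
#' @export
plot_association <- function(data, predictor, outcome) {
  diag <- outlier_diagnostics(data, predictor, outcome)
  df <- tibble::tibble(
    x = data[[predictor]], y = data[[outcome]],
    influential = diag$influential
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "#2166ac", fill = "grey85") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$influential),
                        show.legend = any(df$influential)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "#b2182b")) +
    ggplot2::labs(x = predictor, y = outcome) +
    ggplot2::theme_minimal()
}
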