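#' Plot a power curve
#'
#' Draws rejection frequency against the offset parameter `c` for each
#' method (and panel dimension), from the tidy table produced by
#' [run_power_curve()]. A dashed horizontal line marks the nominal level.
#'
#' @param results Tibble from [run_power_curve()].
#' @param alpha Nominal level to mark (default 0.05).
#' @return A ggplot object.
#' @export
plot_power_curve <- function(results, alpha = 0.05) {
  stopifnot(all(c("c", "value", "method") %in% names(results)))
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$c, y = .data$value,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_grid(model ~ p, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "offset parameter c (per-entry shift c/40)",
                  y = "empirical rejection rate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn test_loadings Histogram of the bootstrap draws with the
#'   observed statistic (solid) and critical value (dashed) marked.
#' @param object A `loading_test`.
#' @export
autoplot.loading_test <- function(object, ...) {
  df <- tibble::tibble(draw = object$draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$critical_value,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "red") +
    ggplot2::labs(x = "bootstrap max statistic", y = "count",
                  title = sprintf(
                    "%s: statistic %.3f vs critical value %.3f (%s)",
                    object$mode, object$statistic, object$critical_value,
                    if (object$reject) "reject" else "do not reject")) +
    ggplot2::theme_minimal()
}

#' @describeIn stepdown_test Per-hypothesis statistics with the final
#'   critical value; rejected hypotheses highlighted.
#' @param object A `stepdown_test`.
#' @export
autoplot.stepdown_test <- function(object, ...) {
  df <- tidy(object)
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$statistic,
                                   colour = .data$rejected)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = object$critical_values[object$n_steps],
      linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "hypothesis index", y = "step-down statistic",
                  colour = "rejected") +
    ggplot2::theme_minimal()
}
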