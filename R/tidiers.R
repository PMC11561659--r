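# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy sandi_age_trend
#' @rdname sandi_tidiers
#' @param x a fitted object.
#' @param ... unused.
tidy.sandi_age_trend <- function(x, ...) {
  f <- function(deg, fit) tibble::tibble(
    degree = deg, term = names(fit$coefficients),
    estimate = unname(fit$coefficients))
  dplyr::bind_rows(f(1L, x$linear), f(2L, x$quadratic))
}

#' Tidiers for fitted sandir objects
#'
#' [tidy()] returns per-term (or per-comparison) tibbles, [glance()] a
#' one-row model summary, following the broom conventions.
#'
#' @return A tibble.
#' @name sandi_tidiers
NULL

#' @export
#' @method glance sandi_age_trend
#' @rdname sandi_tidiers
glance.sandi_age_trend <- function(x, ...) {
  tibble::tibble(metric = x$metric,
                 r_squared_linear = x$linear$r_squared,
                 r_squared_quadratic = x$quadratic$r_squared,
                 peak_age = x$peak_age, concave = x$concave, n = x$n)
}

#' @export
#' @method tidy sandi_group_comparison
#' @rdname sandi_tidiers
tidy.sandi_group_comparison <- function(x, ...) x$posthoc

#' @export
#' @method glance sandi_group_comparison
#' @rdname sandi_tidiers
glance.sandi_group_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric, F = x$ancova$F, df1 = x$ancova$df1,
                 df2 = x$ancova$df2, p = x$ancova$p)
}

#' @export
#' @method tidy sandi_study
#' @rdname sandi_tidiers
tidy.sandi_study <- function(x, ...) x$results_table

#' Heatmap of a correlation results table
#'
#' @param object a `sandi_results_table`.
#' @param ... unused.
#' @return A ggplot object: metric x region tiles coloured by r, starred
#'   where FDR-p < 0.05, facetted by target.
#' @export
#' @method autoplot sandi_results_table
autoplot.sandi_results_table <- function(object, ...) {
  df <- object
  df$label <- sprintf("%.2f%s", df$r, ifelse(df$fdr_p < 0.05, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$metric,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' True-versus-estimated scatter for a recovery experiment
#'
#' @param object a `sandi_recovery` from [run_noise_propagation()].
#' @param ... unused.
#' @return A ggplot object facetted by parameter and SNR.
#' @export
#' @method autoplot sandi_recovery
autoplot.sandi_recovery <- function(object, ...) {
  draws <- attr(object, "draws")
  long <- tidyr::pivot_longer(draws, -c("snr", "iteration"),
                              names_to = c("kind", "parameter"),
                              names_pattern = "(true|est)_(.*)")
  wide <- tidyr::pivot_wider(long, names_from = "kind",
                             values_from = "value")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$true, y = .data$est)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(colour = "red") +
    ggplot2::facet_grid(snr ~ parameter, scales = "free") +
    ggplot2::labs(x = "true", y = "estimated") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a metric against age with linear and quadratic fits
#'
#' @param cohort a cohort tibble (e.g. `study$cohort`) with `age` and the
#'   metric column.
#' @param metric metric column name.
#' @param region optional region filter.
#' @return A ggplot object.
#' @export
plot_age_trend <- function(cohort, metric, region = NULL) {
  df <- if (!is.null(region)) cohort[cohort$region == region, ] else cohort
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data[[metric]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x + I(x^2),
                         se = FALSE, colour = "black", linetype = 2) +
    ggplot2::labs(x = "age (years)", y = metric) +
    ggplot2::theme_minimal()
}
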