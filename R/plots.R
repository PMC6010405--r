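#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot network dissimilarity against time lag
#'
#' Scatter of a pairwise dissimilarity component versus the time lag between
#' sub-networks, with the OLS fit line (drawn on the original lag scale even
#' when the fit used the log-transformed lag).
#'
#' @param pairs Pairwise table from [network_beta_pairs()].
#' @param response Column to plot (default `"beta_wn"`).
#' @param fit Optional `pheno_ols` from [beta_lag_fit()]; fitted without one.
#' @return A ggplot object.
#' @export
plot_beta_lag <- function(pairs, response = "beta_wn", fit = NULL) {
  if (is.null(fit)) fit <- beta_lag_fit(pairs, response = response)
  lagged <- seq(min(pairs$time_lag[pairs$time_lag > 0]), max(pairs$time_lag),
                length.out = 100)
  xfit <- if (fit$transform == "log-lag") log(lagged) else lagged
  line <- tibble::tibble(time_lag = lagged,
                         y = fit$intercept + fit$slope * xfit)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$time_lag,
                                      y = .data[[response]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$y),
                       colour = "firebrick") +
    ggplot2::labs(
      x = "Time lag between sub-networks (days)", y = response,
      subtitle = sprintf("R² = %.2f, p = %.3g (%s)", fit$r_squared,
                         fit$p_value, fit$transform)
    ) +
    ggplot2::theme_minimal()
}

#' Plot within-season module activity
#'
#' Area ("spindle"-style) chart of each module's visits per census day.
#'
#' @param profiles Activity tibble from [module_activity()].
#' @return A ggplot object.
#' @export
plot_module_activity <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$date, y = .data$visits,
                                         fill = .data$module)) +
    ggplot2::geom_area(alpha = 0.8, colour = "grey30", linewidth = 0.2) +
    ggplot2::facet_wrap(~module, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "Census day", y = "Visits received by module plants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @describeIn predict_membership Plot the predicted membership curves.
#' @param object A `module_multinom`.
#' @param ... Unused.
#' @export
autoplot.module_multinom <- function(object, day_grid = NULL, ...) {
  if (is.null(day_grid)) {
    rng <- range(object$fit$model$xc) + object$center
    day_grid <- seq(rng[1], rng[2], length.out = 200)
  }
  pred <- predict_membership(object, day_grid)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$start_day,
                                     y = .data$probability,
                                     colour = .data$module)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "Start day of activity (day of year)",
                  y = "Predicted probability of module membership") +
    ggplot2::theme_minimal()
}

#' Plot flowering overlap against visitor-assemblage dissimilarity
#'
#' @param fit A `pheno_ols` from [overlap_vs_dissimilarity()] (needs its
#'   attached `$data`).
#' @return A ggplot object.
#' @export
plot_overlap_dissimilarity <- function(fit) {
  if (is.null(fit$data)) stop("fit carries no paired data", call. = FALSE)
  ggplot2::ggplot(fit$data, ggplot2::aes(x = .data$s_ij,
                                         y = .data$dissimilarity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "Interspecific flowering overlap", y = "Visitor-assemblage dissimilarity",
      subtitle = sprintf("slope = %.2f, R² = %.2f, p = %.3g", fit$slope,
                         fit$r_squared, fit$p_value)
    ) +
    ggplot2::theme_minimal()
}
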