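# Diagnostic figures.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reward series
#'
#' Per-deck payout-probability trajectories (solid) with the rotating
#' target centers (dashed steps).
#'
#' @param object A `reward_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reward_series <- function(object, ...) {
  df <- as_tibble(object)
  df$deck <- factor(df$deck, labels = paste("deck", 1:3))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, colour = .data$deck)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$payout)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$center), linetype = "dashed",
                       alpha = 0.6) +
    ggplot2::labs(x = "trial", y = "payout probability (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Parameter-recovery scatter plots
#'
#' Generative versus fitted parameter values, one panel per parameter,
#' annotated with the recovery Kendall tau.
#'
#' @param run A `recovery_run`, or a list with `truth`, `fits`,
#'   `recovery` (as returned by [parameter_recovery()]).
#' @return A ggplot.
#' @export
plot_recovery <- function(run) {
  truth <- if (inherits(run, "recovery_run")) run$cohort$truth else
    run$truth
  fits <- run$fits
  keep <- if ("excluded" %in% names(fits)) !fits$excluded else
    rep(TRUE, nrow(fits))
  params <- param_bounds()$param
  df <- purrr::map_dfr(params, function(pm) {
    tibble(param = pm,
           true = truth[[pm]][match(fits$agent[keep], truth$agent)],
           fitted = fits[[pm]][keep])
  })
  labs <- run$recovery
  labs$label <- sprintf("tau = %.2f", labs$tau)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$fitted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = "generative value", y = "fitted value") +
    ggplot2::theme_minimal()
}

#' Population boxplot of probe-regression coefficients
#'
#' @param coefficients Per-agent coefficient tibble (from
#'   [regress_cohort()] or `recovery_run$regression$coefficients`).
#' @return A ggplot.
#' @export
plot_population_coefficients <- function(coefficients) {
  df <- coefficients[coefficients$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "log relative choice odds") +
    ggplot2::theme_minimal()
}
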