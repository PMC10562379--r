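# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a MAP fit
#'
#' @param x A `map_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `unbounded`, `lower`, `upper`.
#' @export
tidy.map_fit <- function(x, ...) {
  b <- param_bounds()
  tibble(term = names(x$params), estimate = unname(x$params),
         unbounded = unname(x$unbounded),
         lower = b$lower, upper = b$upper)
}

#' @rdname tidy.map_fit
#' @return `glance()`: a one-row tibble of fit-level summaries.
#' @export
glance.map_fit <- function(x, ...) {
  tibble(log_likelihood = x$log_likelihood,
         log_posterior = x$log_posterior,
         n_trials = x$n_trials, n_restarts = x$n_restarts,
         n_failed = x$n_failed)
}

#' Tidy a probe-intrusion regression
#'
#' @param x A `probe_regression` object.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, and `deck` for
#'   per-deck fits).
#' @export
tidy.probe_regression <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.probe_regression
#' @export
glance.probe_regression <- function(x, ...) {
  tibble(converged = isTRUE(x$converged), separated = isTRUE(x$separated),
         method = x$method %||% "glm", n = x$n)
}

#' Tidy a recovery run
#'
#' @param x A `recovery_run` object.
#' @param ... Unused.
#' @return The parameter-recovery tibble (`param`, `tau`, `n`, `p_value`).
#' @export
tidy.recovery_run <- function(x, ...) {
  x$recovery
}

#' @rdname tidy.recovery_run
#' @export
glance.recovery_run <- function(x, ...) {
  tibble(n_agents = x$cohort$spec$n, variant = x$cohort$spec$variant,
         n_excluded = sum(x$fits$excluded),
         seed = x$cohort$spec$seed)
}
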