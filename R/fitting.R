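# Maximum a-posteriori fitting of the hybrid model: scaled-logistic
# parameter transforms, truncated priors, random-restart policy, and the
# chance-model exclusion rule.

#' Parameter bounds of the hybrid model
#'
#' @return A tibble with columns `param`, `lower`, `upper`.
#' @export
param_bounds <- function() {
  tibble(
    param = c("alpha_rl", "alpha_sample", "beta_rl", "beta_sample", "beta_p"),
    lower = c(0, 0, 0, 0, -3),
    upper = c(1, 1, 20, 20, 3))
}

#' Map unbounded optimizer coordinates to bounded parameters (and back)
#'
#' The optimizer works on unconstrained real coordinates; each coordinate
#' is mapped into its parameter's interval by a scaled logistic,
#' `lo + (hi - lo) * plogis(u)`, so 0 maps to the interval midpoint.
#' `transform_from_bounds()` is the exact inverse and is undefined (errors)
#' at the interval endpoints, which have no finite preimage.
#'
#' @param u Numeric vector of 5 unbounded values, in [param_bounds()] order.
#' @return `transform_to_bounds()`: a named numeric vector of bounded
#'   parameters; `transform_from_bounds()`: the unbounded coordinates.
#' @export
transform_to_bounds <- function(u) {
  b <- param_bounds()
  stopifnot(length(u) == nrow(b))
  setNames(b$lower + (b$upper - b$lower) * plogis(u), b$param)
}

#' @rdname transform_to_bounds
#' @param p Named or ordered numeric vector of bounded parameter values.
#' @export
transform_from_bounds <- function(p) {
  b <- param_bounds()
  p <- if (!is.null(names(p))) unlist(p[b$param]) else unlist(p)
  stopifnot(length(p) == nrow(b))
  frac <- (p - b$lower) / (b$upper - b$lower)
  if (any(frac <= 0 | frac >= 1))
    stop("values at or beyond the parameter bounds have no finite preimage",
         call. = FALSE)
  setNames(qlogis(frac), b$param)
}

#' Fitting configuration
#'
#' Priors follow the model's defaults: `Beta(1.1, 1.1)` on both learning
#' rates, `Normal(0, 10)` truncated to \[0, 20\] on both inverse
#' temperatures, and `Normal(0, 10)` truncated to \[-3, 3\] on the
#' perseveration weight. Restarts draw starting points uniformly on the
#' unbounded scale in `[-start_range, start_range]` per coordinate and stop
#' once the incumbent optimum has not changed (by more than
#' `stability_tol`) for `stability_count` consecutive runs.
#'
#' @param stability_count Consecutive unchanged runs required to stop.
#' @param max_restarts Hard cap on optimizer runs.
#' @param stability_tol Objective change below which a run counts as
#'   "unchanged".
#' @param reltol Relative convergence tolerance passed to the optimizer.
#' @param start_range Half-width of the uniform start distribution.
#' @param exclusion_alpha Significance level of the chance-model
#'   likelihood-ratio exclusion test.
#' @param flat_prior If `TRUE`, priors are dropped (maximum likelihood);
#'   used for diagnostics.
#' @param seed Integer seed for the restart draws.
#' @return A `fit_config` list.
#' @export
fit_config <- function(stability_count = 5L, max_restarts = 30L,
                       stability_tol = 1e-6, reltol = 1e-8,
                       start_range = 3, exclusion_alpha = 0.05,
                       flat_prior = FALSE, seed = 1L) {
  if (stability_count < 1) stop("`stability_count` must be >= 1", call. = FALSE)
  if (stability_tol <= 0 || reltol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  structure(list(stability_count = as.integer(stability_count),
                 max_restarts = as.integer(max_restarts),
                 stability_tol = stability_tol, reltol = reltol,
                 start_range = start_range,
                 exclusion_alpha = exclusion_alpha,
                 flat_prior = flat_prior, seed = as.integer(seed)),
            class = "fit_config")
}

# Log prior density on the bounded scale; -Inf at zero-density boundaries.
log_prior <- function(p, flat = FALSE) {
  if (flat) return(0)
  ln_trunc_beta <- log(pnorm(20, 0, 10) - pnorm(0, 0, 10))
  ln_trunc_pers <- log(pnorm(3, 0, 10) - pnorm(-3, 0, 10))
  dbeta(p[["alpha_rl"]], 1.1, 1.1, log = TRUE) +
    dbeta(p[["alpha_sample"]], 1.1, 1.1, log = TRUE) +
    (dnorm(p[["beta_rl"]], 0, 10, log = TRUE) - ln_trunc_beta) +
    (dnorm(p[["beta_sample"]], 0, 10, log = TRUE) - ln_trunc_beta) +
    (dnorm(p[["beta_p"]], 0, 10, log = TRUE) - ln_trunc_pers)
}

#' Log posterior on the unbounded scale
#'
#' Sequence log-likelihood at the transformed parameters plus the log
#' prior densities evaluated on the bounded scale. Finite for all interior
#' points; `-Inf` only where a prior density is zero.
#'
#' @param u Unbounded parameter vector (length 5).
#' @param data A choice dataset (see [sequence_log_likelihood()]).
#' @param config A [fit_config()].
#' @return The log posterior (unnormalized).
#' @export
log_posterior <- function(u, data, config = fit_config()) {
  p <- transform_to_bounds(u)
  sequence_log_likelihood(data, as.list(p)) + log_prior(p, config$flat_prior)
}

#' Fit the hybrid model by maximum a-posteriori estimation
#'
#' Optimizes the log posterior over unconstrained coordinates (BFGS),
#' restarting from random starting points until the best objective value
#' has not changed for `stability_count` consecutive runs (or
#' `max_restarts` is reached). Failed optimizer runs are skipped. The same
#' dataset and configuration always yield the same result.
#'
#' @param data A choice dataset with at least one valid learning-phase
#'   choice.
#' @param config A [fit_config()].
#' @return A `map_fit` object: bounded and unbounded estimates, log
#'   posterior, log likelihood at the estimate, restart count, and the
#'   number of valid trials.
#' @export
fit_map <- function(data, config = fit_config()) {
  v <- learning_vectors(data)
  n_valid <- sum(!is.na(v$deck))
  if (n_valid < 1)
    stop("dataset has no valid learning-phase choices", call. = FALSE)
  flat <- config$flat_prior

  # inlined transform + prior (the optimizer calls this thousands of times)
  b <- param_bounds()
  lo <- b$lower
  span <- b$upper - b$lower
  ln_trunc_beta <- log(pnorm(20, 0, 10) - pnorm(0, 0, 10))
  ln_trunc_pers <- log(pnorm(3, 0, 10) - pnorm(-3, 0, 10))
  negpost <- function(u) {
    p <- lo + span * plogis(u)
    ll <- .hybrid_loglik_cpp(v$deck, v$reward, p[1], p[2], p[3], p[4], p[5])
    lp <- if (flat) 0 else
      dbeta(p[1], 1.1, 1.1, log = TRUE) + dbeta(p[2], 1.1, 1.1, log = TRUE) +
      dnorm(p[3], 0, 10, log = TRUE) + dnorm(p[4], 0, 10, log = TRUE) +
      dnorm(p[5], 0, 10, log = TRUE) - 2 * ln_trunc_beta - ln_trunc_pers
    -(ll + lp)
  }

  best <- NULL
  withr::with_seed(config$seed, {
    stable <- 0L
    runs <- 0L
    failed <- 0L
    while (runs < config$max_restarts && stable < config$stability_count) {
      start <- runif(5, -config$start_range, config$start_range)
      runs <- runs + 1L
      opt <- tryCatch(
        optim(start, negpost, method = "BFGS",
              control = list(maxit = 500, reltol = config$reltol)),
        error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$value)) {
        failed <- failed + 1L
        next
      }
      if (is.null(best) || opt$value < best$value - config$stability_tol) {
        best <- opt
        stable <- 0L
      } else {
        if (opt$value < best$value) best <- opt
        stable <- stable + 1L
      }
    }
    if (is.null(best))
      stop("all optimizer restarts failed", call. = FALSE)
    best$runs <- runs
    best$failed <- failed
  })

  params <- transform_to_bounds(best$par)
  ll <- .hybrid_loglik_cpp(v$deck, v$reward,
                           params[["alpha_rl"]], params[["alpha_sample"]],
                           params[["beta_rl"]], params[["beta_sample"]],
                           params[["beta_p"]])
  structure(list(params = params, unbounded = setNames(best$par,
                                                       names(params)),
                 log_posterior = -best$value, log_likelihood = ll,
                 n_restarts = best$runs, n_failed = best$failed,
                 n_trials = n_valid, config = config),
            class = "map_fit")
}

#' @export
print.map_fit <- function(x, ...) {
  cat("<map_fit> log posterior", format(x$log_posterior, digits = 6),
      "| log likelihood", format(x$log_likelihood, digits = 6),
      "|", x$n_restarts, "restarts\n")
  print(round(x$params, 4))
  invisible(x)
}

#' Chance-model exclusion test
#'
#' Likelihood-ratio test of the fitted model against the fixed chance
#' model that assigns probability 1/3 to every deck on every trial
#' (`LL = n * log(1/3)`), on 5 degrees of freedom. Participants whose fit
#' is not significantly better than chance are flagged for exclusion.
#'
#' @param fit A [fit_map()] result.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `excluded`, `p_value`, `lr_statistic`,
#'   `log_likelihood`, `chance_log_likelihood`.
#' @export
exclusion_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "map_fit"))
  ll_chance <- fit$n_trials * log(1 / 3)
  lr <- max(0, 2 * (fit$log_likelihood - ll_chance))
  p <- pchisq(lr, df = 5, lower.tail = FALSE)
  tibble(excluded = p >= alpha, p_value = p, lr_statistic = lr,
         log_likelihood = fit$log_likelihood,
         chance_log_likelihood = ll_chance)
}

#' Fit every agent of a cohort
#'
#' Maps [fit_map()] and [exclusion_test()] over the per-agent choice
#' datasets of a cohort (or a plain list of datasets). Each agent is fit
#' with a seed derived from `config$seed`, so the whole table is
#' reproducible.
#'
#' @param cohort A `bandit_cohort` from [generate_cohort()], or a list of
#'   choice datasets.
#' @param config A [fit_config()].
#' @return A tibble with one row per agent: the five parameter estimates,
#'   `log_likelihood`, `log_posterior`, `n_restarts`, `excluded`,
#'   `exclusion_p`.
#' @export
fit_cohort <- function(cohort, config = fit_config()) {
  datasets <- if (inherits(cohort, "bandit_cohort")) cohort$data else cohort
  n <- length(datasets)
  seeds <- derive_seeds(config$seed, n)
  purrr::map_dfr(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    fit <- fit_map(datasets[[i]], cfg)
    ex <- exclusion_test(fit, alpha = config$exclusion_alpha)
    dplyr::bind_cols(
      tibble(agent = i),
      as_tibble(as.list(fit$params)),
      tibble(log_likelihood = fit$log_likelihood,
             log_posterior = fit$log_posterior,
             n_restarts = fit$n_restarts,
             excluded = ex$excluded, exclusion_p = ex$p_value))
  })
}
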