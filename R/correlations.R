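# Correlation machinery: Kendall tau-b with ties, the sine mapping to
# linear correlations, z-test comparison across samples, and
# age-residualized correlations.

#' Kendall tau-b rank correlation
#'
#' Rank correlation with tie correction, reported because model parameters
#' and behavioral scores exhibit ties. The two-sided p-value uses the
#' standard normal approximation. The result carries the equivalent
#' linear-scale correlation `R = sin(pi * tau / 2)` (see [tau_to_r()]).
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return A one-row tibble: `tau_b`, `n`, `p_value`, `r_equivalent`.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3)
    stop("kendall_tau_b needs at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation is undefined when a variable is entirely tied",
         call. = FALSE)
  ct <- suppressWarnings(
    cor.test(x, y, method = "kendall", exact = FALSE, continuity = FALSE))
  tau <- unname(ct$estimate)
  tibble(tau_b = tau, n = length(x), p_value = ct$p.value,
         r_equivalent = tau_to_r(tau))
}

#' Map Kendall's tau to the equivalent linear correlation
#'
#' `R = sin(0.5 * pi * tau)`, the Greiner relation used before comparing
#' rank correlations on the Fisher-z scale. Odd and monotone, mapping
#' `{-1, 0, 1}` to `{-1, 0, 1}`.
#'
#' @param tau Kendall correlation in \[-1, 1\].
#' @return The linear-scale correlation.
#' @export
tau_to_r <- function(tau) {
  if (any(abs(tau) > 1))
    stop("|tau| must not exceed 1", call. = FALSE)
  sin(0.5 * pi * tau)
}

#' Compare two Kendall correlations across samples
#'
#' Converts both tau values to linear correlations via [tau_to_r()],
#' Fisher-z transforms them, and compares with
#' `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided.
#'
#' @param tau1,tau2 Kendall correlations (|tau| <= 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @return A one-row tibble: `z`, `p_value`, `r1`, `r2`.
#' @export
compare_correlations <- function(tau1, n1, tau2, n2) {
  if (n1 < 4 || n2 < 4)
    stop("both sample sizes must be at least 4", call. = FALSE)
  r1 <- tau_to_r(tau1)
  r2 <- tau_to_r(tau2)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z = z, p_value = 2 * pnorm(-abs(z)), r1 = r1, r2 = r2)
}

#' Age-residualized Kendall correlation
#'
#' Regresses `x` on the covariate by ordinary least squares (with
#' intercept) and correlates the residuals with `y` via
#' [kendall_tau_b()], isolating the part of the `x`-`y` relationship not
#' carried by the covariate. A constant covariate falls back to the plain
#' correlation with a warning. With `both = TRUE`, `y` is residualized as
#' well.
#'
#' @param x,y,covariate Numeric vectors of equal length (>= 4).
#' @param both Residualize both variables.
#' @return A one-row tibble like [kendall_tau_b()], plus `partial = TRUE`.
#' @export
residualized_correlation <- function(x, y, covariate, both = FALSE) {
  stopifnot(length(x) == length(y), length(x) == length(covariate))
  if (length(x) < 4)
    stop("residualized correlation needs at least 4 observations",
         call. = FALSE)
  if (sd(covariate, na.rm = TRUE) == 0) {
    warning("constant covariate; returning the plain correlation")
    return(dplyr::mutate(kendall_tau_b(x, y), partial = FALSE))
  }
  rx <- resid(lm(x ~ covariate))
  ry <- if (both) resid(lm(y ~ covariate)) else y
  dplyr::mutate(kendall_tau_b(rx, ry), partial = TRUE)
}

#' Headline lifespan correlations of a fitted cohort
#'
#' Joins fitted parameters, LDI scores, and cohort covariates, and
#' computes the correlations the lifespan analysis turns on: LDI with the
#' memory-sampling weight (also after age residualization), and age with
#' the RL weight and the perseveration weight.
#'
#' @param fits Per-agent parameter tibble from [fit_cohort()].
#' @param ldi Per-agent LDI tibble from [score_mst_cohort()].
#' @param covariates Cohort truth/covariate tibble (needs `agent`, `age`).
#' @param include_excluded Keep agents flagged by the chance-model
#'   exclusion rule (default drops them).
#' @return A tidy tibble: `pair`, `tau_b`, `n`, `p_value`,
#'   `r_equivalent`, `partial`.
#' @export
correlate_cohort <- function(fits, ldi, covariates,
                             include_excluded = FALSE) {
  d <- fits |>
    dplyr::left_join(ldi, by = "agent") |>
    dplyr::left_join(dplyr::select(covariates, "agent", "age"), by = "agent")
  if (!include_excluded && "excluded" %in% names(d))
    d <- d[!d$excluded, , drop = FALSE]
  row <- function(pair, res) {
    if (!"partial" %in% names(res)) res$partial <- FALSE
    res$pair <- pair
    dplyr::select(res, "pair", "tau_b", "n", "p_value", "r_equivalent",
                  "partial")
  }
  dplyr::bind_rows(
    row("ldi~beta_sample", kendall_tau_b(d$ldi, d$beta_sample)),
    row("ldi~beta_sample|age",
        residualized_correlation(d$beta_sample, d$ldi, d$age)),
    row("age~beta_rl", kendall_tau_b(d$age, d$beta_rl)),
    row("age~beta_p", kendall_tau_b(d$age, d$beta_p)))
}
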