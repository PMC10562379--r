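# Orchestration and file interchange: choice-data CSV round-trip, the
# end-to-end recovery pipeline, and its run record.

choice_csv_cols <- function() {
  readr::cols(
    slot = readr::col_integer(),
    phase = readr::col_integer(),
    trial_type = readr::col_character(),
    choice_trial = readr::col_integer(),
    room = readr::col_integer(),
    context_id = readr::col_character(),
    category = readr::col_character(),
    deck = readr::col_integer(),
    reward = readr::col_integer(),
    probe_kind = readr::col_character(),
    probe_ref = readr::col_integer(),
    probe_response = readr::col_character())
}

#' Write / read a choice dataset as plain CSV
#'
#' Trial-level interchange format: one row per slot, 1-based trial
#' columns, schema-validated on read with errors naming the offending row.
#'
#' @param dataset A choice-dataset tibble.
#' @param path File path.
#' @return `read_choice_csv()` returns the dataset tibble;
#'   `write_choice_csv()` returns `path` invisibly.
#' @export
write_choice_csv <- function(dataset, path) {
  cols <- names(choice_csv_cols()$cols)
  missing <- setdiff(cols, names(dataset))
  if (length(missing) > 0)
    stop("dataset is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  readr::write_csv(dataset[cols], path, na = "")
  invisible(path)
}

#' @rdname write_choice_csv
#' @export
read_choice_csv <- function(path) {
  d <- readr::read_csv(path, col_types = choice_csv_cols(), na = "",
                       progress = FALSE)
  cols <- names(choice_csv_cols()$cols)
  missing <- setdiff(cols, names(d))
  if (length(missing) > 0)
    stop("file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad_deck <- which(!is.na(d$deck) & !d$deck %in% 1:3)
  if (length(bad_deck) > 0)
    stop(sprintf("invalid deck value in row %d (must be 1-3)", bad_deck[1]),
         call. = FALSE)
  bad_rwd <- which(!is.na(d$reward) & !d$reward %in% 0:1)
  if (length(bad_rwd) > 0)
    stop(sprintf("invalid reward value in row %d (must be 0/1)", bad_rwd[1]),
         call. = FALSE)
  bad_ref <- which(!is.na(d$probe_ref) & d$probe_ref < 1)
  if (length(bad_ref) > 0)
    stop(sprintf("invalid probe reference in row %d", bad_ref[1]),
         call. = FALSE)
  d
}

#' Run the full recovery pipeline on a synthetic cohort
#'
#' Composes every analysis stage end to end: generate the cohort, fit the
#' hybrid model per agent (with chance-model exclusions), run the
#' probe-intrusion regression and its population tests, score the MST into
#' LDI, compute the headline lifespan correlations, and score parameter
#' recovery (Kendall correlation between generative and fitted values per
#' parameter, over retained agents). Optionally writes every stage's table
#' to CSV under `out_dir` along with a plain-text run record (config,
#' seeds, timings), making a completed run reproducible from its record.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional output directory (created if needed).
#' @param config A [fit_config()].
#' @param include_gist Include the gist regressor (defaults to variant 2).
#' @return A `recovery_run` list: `cohort`, `fits`, `regression`,
#'   `ldi`, `correlations`, `recovery`, `record`.
#' @export
run_recovery <- function(spec, out_dir = NULL, config = fit_config(),
                         include_gist = spec$variant == 2) {
  t0 <- Sys.time()
  cohort <- generate_cohort(spec)
  t1 <- Sys.time()
  fits <- fit_cohort(cohort, config)
  t2 <- Sys.time()
  regression <- regress_cohort(cohort, include_gist = include_gist)
  t3 <- Sys.time()
  ldi <- score_mst_cohort(cohort)
  correlations <- correlate_cohort(fits, ldi, cohort$truth)
  recovery <- score_recovery(cohort$truth, fits)
  t4 <- Sys.time()

  record <- tibble(
    field = c("n", "variant", "master_seed", "fit_seed", "include_gist",
              "n_excluded", "time_generate_s", "time_fit_s",
              "time_regress_s", "time_score_s", "package_version"),
    value = c(spec$n, spec$variant, spec$seed, config$seed, include_gist,
              sum(fits$excluded),
              round(as.numeric(t1 - t0, units = "secs"), 2),
              round(as.numeric(t2 - t1, units = "secs"), 2),
              round(as.numeric(t3 - t2, units = "secs"), 2),
              round(as.numeric(t4 - t3, units = "secs"), 2),
              as.character(utils::packageVersion("membandit"))))

  run <- structure(list(cohort = cohort, fits = fits,
                        regression = regression, ldi = ldi,
                        correlations = correlations, recovery = recovery,
                        record = record),
                   class = "recovery_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(cohort$data))
      write_choice_csv(cohort$data[[i]],
                       file.path(out_dir, sprintf("choices_agent%03d.csv", i)))
    readr::write_csv(cohort$truth, file.path(out_dir, "truth.csv"))
    readr::write_csv(fits, file.path(out_dir, "fits.csv"))
    readr::write_csv(regression$coefficients,
                     file.path(out_dir, "regression_coefficients.csv"))
    readr::write_csv(regression$population,
                     file.path(out_dir, "regression_population.csv"))
    readr::write_csv(ldi, file.path(out_dir, "ldi.csv"))
    readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))
    readr::write_csv(recovery, file.path(out_dir, "recovery.csv"))
    readr::write_csv(record, file.path(out_dir, "run_record.csv"))
  }
  run
}

#' Parameter-recovery score of a fitted cohort
#'
#' Kendall tau-b between generative and fitted values for each of the five
#' parameters, over agents retained by the exclusion rule.
#'
#' @param truth Cohort truth tibble (per-agent generative parameters).
#' @param fits Per-agent fit tibble from [fit_cohort()].
#' @return A tibble: `param`, `tau`, `n`, `p_value`.
#' @export
score_recovery <- function(truth, fits) {
  keep <- if ("excluded" %in% names(fits)) !fits$excluded else
    rep(TRUE, nrow(fits))
  params <- param_bounds()$param
  purrr::map_dfr(params, function(pm) {
    tv <- truth[[pm]][match(fits$agent[keep], truth$agent)]
    fv <- fits[[pm]][keep]
    res <- kendall_tau_b(tv, fv)
    tibble(param = pm, tau = res$tau_b, n = res$n, p_value = res$p_value)
  })
}

#' @export
print.recovery_run <- function(x, ...) {
  cat(sprintf("<recovery_run> %d agents (variant %d), %d excluded\n",
              x$cohort$spec$n, x$cohort$spec$variant,
              sum(x$fits$excluded)))
  cat("parameter recovery (Kendall tau, retained agents):\n")
  print(x$recovery)
  cat("headline correlations:\n")
  print(x$correlations)
  invisible(x)
}

#' Parameter-recovery experiment with parameters spanning the full ranges
#'
#' Simulates `n_agents` learning phases with parameters drawn uniformly
#' across each parameter's full bounded range (each agent on its own
#' schedule and reward walk), fits each by MAP, and scores recovery. This
#' is the designed stress test of the fitting machinery, distinct from the
#' lifespan cohort whose parameters occupy narrower, realistic ranges.
#'
#' @param n_agents Number of simulated agents.
#' @param seed Master seed.
#' @param config A [fit_config()].
#' @param variant Experiment variant for the task structure.
#' @return A list with `truth`, `fits`, and `recovery` tibbles.
#' @export
parameter_recovery <- function(n_agents = 100L, seed = 1L,
                               config = fit_config(), variant = 1) {
  b <- param_bounds()
  seeds <- derive_seeds(seed, 3L * n_agents + 1L)
  truth <- withr::with_seed(seeds[1], {
    draws <- purrr::map(seq_len(nrow(b)),
                        ~runif(n_agents, b$lower[.x], b$upper[.x]))
    names(draws) <- b$param
    dplyr::bind_cols(tibble(agent = seq_len(n_agents)), as_tibble(draws))
  })
  datasets <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    schedule <- build_schedule(variant, seed = seeds[3 * i - 1])
    series <- generate_reward_walk(reward_walk_config(), schedule,
                                   seed = seeds[3 * i])
    gp <- generative_params(
      agent_params(truth$alpha_rl[i], truth$alpha_sample[i],
                   truth$beta_rl[i], truth$beta_sample[i], truth$beta_p[i]))
    datasets[[i]] <- simulate_learning_phase(gp, series, schedule,
                                             seed = seeds[3 * i + 1])
  }
  fits <- fit_cohort(datasets, config)
  list(truth = truth, fits = fits,
       recovery = score_recovery(truth, fits))
}
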