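# Probe-intrusion regression: evoked context reward, design matrix,
# orthogonalization, fitting, population tests.

test_that("evoked context reward counts wins minus losses per choice", {
  d <- make_learning_rows(deck = c(1, 1, 1, 1, 2, 2),
                          reward = c(1, 1, 1, 0, 1, 0))
  expect_equal(evoked_context_reward(d, 1, 1), 0.5)   # 3 wins, 1 loss
  expect_equal(evoked_context_reward(d, 1, 2), 0)     # 1 win, 1 loss
  expect_equal(evoked_context_reward(d, 1, 3), 0)     # never chosen
  all_win <- make_learning_rows(rep(2, 5), rep(1, 5))
  expect_equal(evoked_context_reward(all_win, 1, 2), 1)
  all_loss <- make_learning_rows(rep(2, 5), rep(0, 5))
  expect_equal(evoked_context_reward(all_loss, 1, 2), -1)
  expect_error(evoked_context_reward(d, 9, 1), "room")
  expect_error(evoked_context_reward(d, 1, 5), "deck")
})

test_that("design matrix has the stated shape and zero probe terms off
           post-probe trials", {
  env <- make_env(seed = 2, walk_seed = 3)
  gp <- generative_params(agent_params(0.4, 0.5, 6, 3, 0.5),
                          b_item = 0.5, b_ctx = 1)
  d <- simulate_agent(gp, env$series, env$schedule, seed = 4)
  dm <- build_design_matrix(d, env$schedule)
  expect_equal(nrow(dm), 360)
  expect_equal(setdiff(names(dm), c("choice_trial", "deck", "chosen")),
               c("di", "dr1", "dr2", "dr3", "ei", "er", "ec"))
  # responses across the three deck rows sum to one per trial
  per_trial <- tapply(dm$chosen, dm$choice_trial, sum)
  expect_true(all(per_trial == 1))
  # probe columns live only on trials right after an old probe
  tr <- env$schedule$trials
  p2 <- tr[tr$phase == 2, ]
  after_old <- p2$choice_trial[
    c(FALSE, p2$trial_type[-nrow(p2)] == "probe" &
        p2$probe_kind[-nrow(p2)] == "old")]
  off <- !dm$choice_trial %in% after_old
  expect_true(all(dm$ei[off] == 0))
  expect_true(all(dm$er[off] == 0))
  expect_true(all(dm$ec[off] == 0))
  expect_true(any(dm$ei != 0))
  # binary regressors and bounded EC
  for (cl in c("di", "dr1", "dr2", "dr3", "ei", "er"))
    expect_true(all(dm[[cl]] %in% 0:1))
  expect_true(all(abs(dm$ec) <= 1))
})

test_that("gist column is exactly orthogonal to the target column", {
  env <- make_env(variant = 2, seed = 5, walk_seed = 6)
  gp <- generative_params(agent_params(0.4, 0.5, 6, 3, 0.5),
                          b_item = 0.3, b_ctx = 1, b_gist = 0.5)
  d <- simulate_agent(gp, env$series, env$schedule, seed = 7)
  dm <- build_design_matrix(d, env$schedule, include_gist = TRUE)
  expect_equal(nrow(dm), 360)
  expect_true("ec_gist" %in% names(dm))
  expect_lt(abs(sum(dm$ec * dm$ec_gist)), 1e-10)
  # and requesting gist on a variant 1 schedule is a usage error
  env1 <- make_env(seed = 5, walk_seed = 6)
  d1 <- simulate_agent(gp, env1$series, env1$schedule, seed = 7)
  expect_error(build_design_matrix(d1, env1$schedule, include_gist = TRUE),
               "variant 2")
})

test_that("serial orthogonalization projects without centering", {
  expect_equal(orthogonalize_serial(c(1, 0), c(1, 1)), c(0, 1))
  g <- c(3, -2, 5)
  expect_equal(orthogonalize_serial(g, g), rep(0, 3))
  t1 <- c(1, 1, 0)
  g1 <- c(0, 0, 2)
  expect_equal(orthogonalize_serial(t1, g1), g1, tolerance = 1e-12)
  expect_warning(out <- orthogonalize_serial(rep(0, 3), g), "zero norm")
  expect_equal(out, g)
})

test_that("all-zero regressors give a pure-intercept fit with zero slopes", {
  dm <- tibble::tibble(
    choice_trial = rep(1:40, each = 3), deck = rep(1:3, 40),
    chosen = as.integer(rep(1:3, 40) == rep(rep(1:3, length.out = 40),
                                            each = 3)),
    di = 0L, dr1 = 0L, dr2 = 0L, dr3 = 0L, ei = 0L, er = 0L, ec = 0)
  class(dm) <- c("probe_design", class(dm))
  attr(dm, "include_gist") <- FALSE
  fit <- fit_probe_regression(dm)
  cf <- tidy(fit)
  slopes <- cf$estimate[cf$term != "(Intercept)"]
  expect_true(all(abs(slopes) < 1e-6))
  expect_equal(cf$estimate[cf$term == "(Intercept)"], qlogis(1 / 3),
               tolerance = 0.05)
})

test_that("maximum-likelihood coefficients are invariant to row
           duplication", {
  env <- make_env(seed = 8, walk_seed = 9)
  gp <- generative_params(agent_params(0.4, 0.5, 4, 2, 0.3), b_ctx = 1)
  d <- simulate_agent(gp, env$series, env$schedule, seed = 10)
  dm <- build_design_matrix(d, env$schedule)
  f1 <- fit_probe_regression(dm)
  dm2 <- dplyr::bind_rows(dm, dm)
  class(dm2) <- class(dm)
  attr(dm2, "include_gist") <- FALSE
  f2 <- fit_probe_regression(dm2)
  expect_false(f1$separated)  # this fixture fits cleanly by ML
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-6)
})

test_that("population test behaves at symmetric, strong, and degenerate
           inputs", {
  sym <- c(-2, -1, 1, 2)
  expect_equal(population_test(sym)$p_value, 1)
  set.seed(9)
  strong <- 1 + rnorm(30, 0, 0.01)
  expect_lt(population_test(strong)$p_value, 1e-6)
  expect_equal(population_test(c(-1, 1))$statistic, 0)
  expect_error(population_test(c(1, 1, 1)), "zero-variance")
  expect_error(population_test(1), "at least 2")
})

test_that("a context-biased generator is recovered as a positive EC
           coefficient that dominates the probe terms", {
  co <- generate_cohort(cohort_spec(n = 30, seed = 44, b_item = 0,
                                    b_ctx = 1, b_gist = 0))
  reg <- regress_cohort(co)
  pop <- reg$population
  ec_row <- pop[pop$term == "ec", ]
  expect_gt(ec_row$estimate, 0)
  expect_lt(ec_row$p_value, 0.05)
  probe_means <- abs(pop$estimate[pop$term %in% c("ei", "er", "ec")])
  expect_equal(pop$term[pop$term %in% c("ei", "er", "ec")][
    which.max(probe_means)], "ec")
})

test_that("per-deck fitting returns one coefficient set per deck", {
  env <- make_env(seed = 12, walk_seed = 13)
  gp <- generative_params(agent_params(0.4, 0.5, 4, 2, 0.3), b_ctx = 1)
  d <- simulate_agent(gp, env$series, env$schedule, seed = 14)
  dm <- build_design_matrix(d, env$schedule)
  f <- fit_probe_regression(dm, per_deck = TRUE)
  expect_equal(sort(unique(tidy(f)$deck)), 1:3)
})
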