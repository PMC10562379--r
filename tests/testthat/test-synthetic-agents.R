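# Synthetic agents: generative simulation of both phases, MST responses,
# cohort assembly.

test_that("a zero-weight agent chooses each deck a third of the time", {
  counts <- c(0, 0, 0)
  gp <- generative_params(agent_params(0.5, 0.5, 0, 0, 0))
  for (s in 1:20) {
    env <- make_env(seed = 1100 + s, walk_seed = 1200 + s)
    d <- simulate_learning_phase(gp, env$series, env$schedule, seed = s)
    counts <- counts + tabulate(d$deck, 3)
  }
  freqs <- counts / sum(counts)
  se3 <- 3 * sqrt((1 / 3) * (2 / 3) / sum(counts))
  expect_true(all(abs(freqs - 1 / 3) < se3 + 0.005))
})

test_that("a hot RL agent tracks the highest-paying deck in stable blocks", {
  cfg <- reward_walk_config(noise_sd = 0)
  hits <- 0
  tot <- 0
  for (s in 1:10) {
    sch <- build_schedule(1, seed = 1300 + s)
    ser <- generate_reward_walk(cfg, sch, seed = 1400 + s)
    gp <- generative_params(agent_params(0.5, 0.5, 20, 0, 0))
    d <- simulate_learning_phase(gp, ser, sch, seed = s)
    cm <- payout_matrix(ser, "center")
    best <- apply(cm, 2, which.max)
    # settle-in window: last 15 trials of each stable 30-trial segment
    idx <- unlist(lapply(seq(11, 151, by = 30), function(b) b + 15:29))
    hits <- hits + sum(d$deck[idx] == best[idx])
    tot <- tot + length(idx)
  }
  expect_gt(hits / tot, 0.5)
})

test_that("simulation is reproducible from its seed", {
  env <- make_env(variant = 2, seed = 6, walk_seed = 7)
  gp <- generative_params(agent_params(0.4, 0.5, 6, 3, 0.5),
                          b_item = 0.5, b_ctx = 1, b_gist = 0.5,
                          probe_recognition_accuracy = 0.8)
  d1 <- simulate_agent(gp, env$series, env$schedule, seed = 9)
  d2 <- simulate_agent(gp, env$series, env$schedule, seed = 9)
  expect_identical(d1, d2)
  m1 <- simulate_mst(0.6, seed = 4)
  m2 <- simulate_mst(0.6, seed = 4)
  expect_identical(m1, m2)
})

test_that("probe-phase data respects the schedule and the walk", {
  env <- make_env(seed = 10, walk_seed = 11)
  gp <- generative_params(agent_params(0.4, 0.5, 6, 3, 0.5),
                          b_item = 0.5, b_ctx = 1)
  d <- simulate_agent(gp, env$series, env$schedule, seed = 12)
  expect_equal(nrow(d), 360)
  p2 <- d[d$phase == 2, ]
  expect_true(all(is.na(p2$deck[p2$trial_type == "probe"])))
  expect_true(all(!is.na(p2$deck[p2$trial_type == "choice"])))
  expect_true(all(p2$probe_response[p2$trial_type == "probe"] %in%
                    c("old", "new")))
  refs <- p2$probe_ref[!is.na(p2$probe_ref)]
  expect_true(all(refs %in% 1:180))
})

test_that("perfect probe recognition labels old and novel probes exactly", {
  env <- make_env(seed = 13, walk_seed = 14)
  gp <- generative_params(agent_params(), probe_recognition_accuracy = 1)
  d <- simulate_agent(gp, env$series, env$schedule, seed = 15)
  pr <- d[d$trial_type == "probe", ]
  expect_true(all(pr$probe_response[pr$probe_kind == "old"] == "old"))
  expect_true(all(pr$probe_response[pr$probe_kind == "novel"] == "new"))
})

test_that("with zero probe biases, post-probe choices look like other
           phase-2 choices", {
  post <- c(0, 0, 0)
  other <- c(0, 0, 0)
  gp <- generative_params(agent_params(0.4, 0.5, 4, 2, 0.3),
                          b_item = 0, b_ctx = 0)
  for (s in 1:60) {
    env <- make_env(seed = 1500 + s, walk_seed = 1600 + s)
    d <- simulate_agent(gp, env$series, env$schedule, seed = s)
    p2 <- d[d$phase == 2, ]
    after_probe <- c(FALSE, p2$trial_type[-nrow(p2)] == "probe")
    is_choice <- p2$trial_type == "choice"
    post <- post + tabulate(p2$deck[is_choice & after_probe], 3)
    other <- other + tabulate(p2$deck[is_choice & !after_probe], 3)
  }
  pval <- chisq.test(rbind(post, other))$p.value
  expect_gt(pval, 0.001)
})

test_that("MST generator emits the standard list structure", {
  m <- simulate_mst(0.5, seed = 3)
  expect_equal(nrow(m$study), 128)
  expect_equal(nrow(m$test), 192)
  expect_equal(as.vector(table(m$test$condition)), rep(64L, 3))
  expect_true(all(m$test$response %in% c("old", "similar", "new")))
})

test_that("MST response model has the documented closed form", {
  for (p in c(0, 0.3, 1)) {
    probs <- mst_response_probs(p)
    expect_equal(rowSums(probs), rep(1, 3), ignore_attr = TRUE)
    expect_true(all(probs >= 0))
    expect_equal(expected_ldi(p),
                 probs["lure", "similar"] - probs["foil", "similar"])
  }
  expect_equal(expected_ldi(0), 0)  # lure and foil equally often 'similar'
})

test_that("realized LDI tracks precision monotonically over a grid", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  ldis <- vapply(seq_along(grid), function(i) {
    m <- simulate_mst(grid[i], seed = 40 + i, n_test = 999)
    compute_ldi(m)$ldi
  }, numeric(1))
  expect_true(all(diff(ldis) > 0))
  # at full precision, realized LDI is within binomial error of its
  # expectation
  m1 <- simulate_mst(1, seed = 50, n_test = 999)
  expect_lt(abs(compute_ldi(m1)$ldi - expected_ldi(1)), 0.1)
})

test_that("cohorts are reproducible, sized, and directionally structured", {
  expect_equal(length(generate_cohort(cohort_spec(n = 0))$data), 0)

  c1 <- generate_cohort(cohort_spec(n = 4, seed = 12))
  c2 <- generate_cohort(cohort_spec(n = 4, seed = 12))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$data, c2$data)
  expect_identical(c1$mst, c2$mst)

  tr <- withr::with_seed(3, membandit:::cohort_draw_covariates(
    cohort_spec(n = 200)))
  expect_lt(kendall_tau_b(tr$age, tr$beta_rl)$tau_b, 0)
  expect_gt(kendall_tau_b(tr$age, tr$beta_p)$tau_b, 0)
  expect_gt(kendall_tau_b(tr$precision, tr$beta_sample)$tau_b, 0)
  expect_lt(kendall_tau_b(tr$age, tr$precision)$tau_b, 0)
})

test_that("ground-truth precision shows up in realized LDI", {
  co <- generate_cohort(cohort_spec(n = 100, seed = 31))
  ldi <- score_mst_cohort(co)
  res <- kendall_tau_b(co$truth$precision, ldi$ldi)
  expect_gt(res$tau_b, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("simulated data is likeliest near its generating parameters", {
  wins_up <- 0
  wins_dn <- 0
  n_agents <- 50
  for (s in 1:n_agents) {
    env <- make_env(seed = 1700 + s, walk_seed = 1800 + s)
    ap <- agent_params(0.4, 0.5, 6, 4, 0.8)
    gp <- generative_params(ap)
    d <- simulate_learning_phase(gp, env$series, env$schedule, seed = s)
    ll_true <- sequence_log_likelihood(d, ap)
    up <- agent_params(min(1, 0.4 * 1.5), min(1, 0.5 * 1.5), 9, 6, 1.2)
    dn <- agent_params(0.2, 0.25, 3, 2, 0.4)
    if (ll_true > sequence_log_likelihood(d, up)) wins_up <- wins_up + 1
    if (ll_true > sequence_log_likelihood(d, dn)) wins_dn <- wins_dn + 1
  }
  # sign test at 5%: at least 32/50 successes
  expect_gte(wins_up, 32)
  expect_gte(wins_dn, 32)
})
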