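# Independent oracles and small fixture builders used across the suite.

# Brute-force memory-sampler expectation: evaluate the recency kernel
# alpha * (1 - alpha)^(t - i) at every past choice, normalize, average.
brute_sampler_value <- function(trials, rewards, alpha, t) {
  w <- alpha * (1 - alpha)^(t - trials)
  if (alpha == 1) {
    w <- rep(0, length(trials))
    w[which.max(trials)] <- 1
  }
  sum(w * rewards) / sum(w)
}

# All-pairs Kendall tau-b with tie correction.
brute_tau_b <- function(x, y) {
  n <- length(x)
  conc <- 0
  disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    tt <- table(v)
    sum(tt * (tt - 1) / 2)
  }
  (conc - disc) / sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
}

# Trial-by-trial R-level composition of the hybrid model, used as the
# independent oracle for the compiled likelihood.
compose_loglik <- function(deck, reward, params) {
  v <- rep(0, 3)
  hist <- lapply(1:3, function(i) data.frame(trial = integer(),
                                             reward = integer()))
  prev <- NA
  ll <- 0
  for (t in seq_along(deck)) {
    if (is.na(deck[t])) {
      prev <- NA
      next
    }
    vs <- vapply(1:3, function(i) sampler_value(hist[[i]],
                                                params$alpha_sample, t),
                 numeric(1))
    pr <- choice_probabilities(v, vs, prev, params)
    ll <- ll + log(pr[deck[t]])
    v <- rl_update(v, deck[t], reward[t], params$alpha_rl)
    hist[[deck[t]]] <- rbind(hist[[deck[t]]],
                             data.frame(trial = t, reward = reward[t]))
    prev <- deck[t]
  }
  ll
}

# Small simulated environment shared by several tests.
make_env <- function(variant = 1, seed = 1, walk_seed = 2) {
  schedule <- build_schedule(variant, seed = seed)
  series <- generate_reward_walk(reward_walk_config(), schedule,
                                 seed = walk_seed)
  if (variant == 2) series <- assign_lure_opposed_walks(series, schedule)
  list(schedule = schedule, series = series)
}

# Minimal learning-phase table for hand-built examples.
make_learning_rows <- function(deck, reward, room = 1) {
  tibble::tibble(
    slot = seq_along(deck), phase = 1L, trial_type = "choice",
    choice_trial = seq_along(deck), room = room,
    context_id = paste0("scene", room), category = NA_character_,
    probe_kind = NA_character_, probe_ref = NA_integer_,
    deck = as.integer(deck), reward = as.integer(reward),
    probe_response = NA_character_)
}
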