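# Synthetic-data generator: hybrid agents simulated through both task
# phases, a three-state MST response model with a precision dial, and
# lifespan cohorts with the covariate structure the analyses assume.

#' Generative parameters for a simulated agent
#'
#' The five choice-model parameters plus generative-only probe-bias
#' weights, applied additively in logits on the choice trial immediately
#' following an old-item probe: `b_item` on the probed deck's identity,
#' `b_ctx` on each deck's evoked context reward in the probed room, and
#' (variant 2) `b_gist` on each deck's evoked reward pooled over the
#' probed room and its same-category foil. The additive-logit form mirrors
#' the linear-in-logit intrusion regression, giving the analysis stage a
#' well-posed recovery target.
#'
#' @param params An [agent_params()] object.
#' @param b_item,b_ctx,b_gist Probe-bias weights (logit units).
#' @param probe_recognition_accuracy Probability of a correct old/new
#'   judgment on probe trials, in \[0, 1\].
#' @return A `generative_params` list.
#' @export
generative_params <- function(params = agent_params(),
                              b_item = 0, b_ctx = 0, b_gist = 0,
                              probe_recognition_accuracy = 0.9) {
  stopifnot(is.finite(b_item), is.finite(b_ctx), is.finite(b_gist),
            probe_recognition_accuracy >= 0, probe_recognition_accuracy <= 1)
  structure(list(params = params, b_item = b_item, b_ctx = b_ctx,
                 b_gist = b_gist,
                 probe_recognition_accuracy = probe_recognition_accuracy),
            class = "generative_params")
}

# --- internal hybrid agent state (mirrors the compiled likelihood loop) ---

hybrid_state_new <- function() {
  list(v_rl = rep(0, 3), num = rep(0, 3), den = rep(0, 3),
       last = rep(NA_integer_, 3), prev = NA_integer_)
}

hybrid_state_values <- function(st) {
  vs <- ifelse(st$den > 0, st$num / st$den, 0)
  list(v_rl = st$v_rl, v_sample = vs)
}

hybrid_state_update <- function(st, deck, reward, t, params) {
  st$v_rl[deck] <- st$v_rl[deck] + params$alpha_rl * (reward - st$v_rl[deck])
  if (is.na(st$last[deck])) {
    st$num[deck] <- reward
    st$den[deck] <- 1
  } else {
    decay <- (1 - params$alpha_sample)^(t - st$last[deck])
    st$num[deck] <- st$num[deck] * decay + reward
    st$den[deck] <- st$den[deck] * decay + 1
  }
  st$last[deck] <- t
  st$prev <- deck
  st
}

# replay recorded choices to recover the agent state after the last trial
hybrid_state_replay <- function(deck, reward, params) {
  st <- hybrid_state_new()
  for (t in seq_along(deck)) {
    if (is.na(deck[t])) {
      st$prev <- NA_integer_
      next
    }
    st <- hybrid_state_update(st, deck[t], reward[t], t, params)
  }
  st
}

#' Simulate the learning phase of one agent
#'
#' Runs the hybrid policy generatively over the 180 learning trials: on
#' each trial the choice probabilities are computed from the current TD
#' and sampler values (expectation form, the same values the likelihood
#' uses), a choice is drawn, and the reward is Bernoulli with the chosen
#' deck's current payout probability.
#'
#' @param gparams A [generative_params()] object.
#' @param series A `reward_series` for the schedule.
#' @param schedule A [build_schedule()] object.
#' @param seed Integer seed.
#' @return A choice-dataset tibble (learning-phase rows).
#' @export
simulate_learning_phase <- function(gparams, series, schedule, seed = 1L) {
  stopifnot(inherits(gparams, "generative_params"))
  pm <- payout_matrix(series)
  p1 <- schedule$trials[schedule$trials$phase == 1, ]
  n <- nrow(p1)
  ap <- gparams$params
  deck <- integer(n)
  reward <- integer(n)
  withr::with_seed(seed, {
    st <- hybrid_state_new()
    for (t in seq_len(n)) {
      vals <- hybrid_state_values(st)
      pr <- choice_probabilities(vals$v_rl, vals$v_sample, st$prev, ap)
      d <- sample.int(3L, 1L, prob = pr)
      r <- rbinom(1L, 1L, pm[d, t] / 100)
      deck[t] <- d
      reward[t] <- r
      st <- hybrid_state_update(st, d, r, t, ap)
    }
  })
  out <- p1
  out$deck <- deck
  out$reward <- reward
  out$probe_response <- NA_character_
  out
}

#' Simulate the probe phase of one agent
#'
#' Continues the agent through the 180 phase-2 slots. Probe trials draw an
#' old/new recognition response with the agent's
#' `probe_recognition_accuracy`. On the choice trial immediately following
#' an old-item probe, deck logits additionally receive the agent's
#' probe-bias terms (see [generative_params()]), computed from the agent's
#' own learning-phase experience. Rewards follow the walk, which continues
#' through phase 2.
#'
#' @inheritParams simulate_learning_phase
#' @param learning_data The agent's simulated learning phase.
#' @return A choice-dataset tibble (phase-2 rows).
#' @export
simulate_probe_phase <- function(gparams, learning_data, series, schedule,
                                 seed = 1L) {
  stopifnot(inherits(gparams, "generative_params"))
  pm <- payout_matrix(series)
  p2 <- schedule$trials[schedule$trials$phase == 2, ]
  ap <- gparams$params
  acc <- gparams$probe_recognition_accuracy

  ec_tab <- evoked_context_table(learning_data)
  ec_mat <- matrix(ec_tab$ec, nrow = schedule$n_rooms, byrow = TRUE)
  gist_mat <- NULL
  if (schedule$variant == 2 && gparams$b_gist != 0) {
    gt <- evoked_gist_table(learning_data, schedule)
    gist_mat <- matrix(gt$ec_gist, ncol = 3, byrow = TRUE,
                       dimnames = list(unique(gt$category), NULL))
  }
  ldeck <- learning_data$deck
  lreward <- learning_data$reward
  lroom <- learning_data$room
  lcat <- learning_data$category

  n <- nrow(p2)
  deck <- rep(NA_integer_, n)
  reward <- rep(NA_integer_, n)
  presp <- rep(NA_character_, n)
  withr::with_seed(seed, {
    st <- hybrid_state_replay(ldeck, lreward, ap)
    pending <- NULL  # probe carried into the next choice trial
    for (k in seq_len(n)) {
      if (p2$trial_type[k] == "probe") {
        correct <- runif(1) < acc
        if (p2$probe_kind[k] == "old") {
          presp[k] <- if (correct) "old" else "new"
          ref <- p2$probe_ref[k]
          if (!is.na(ldeck[ref]))
            pending <- list(deck = ldeck[ref], reward = lreward[ref],
                            room = lroom[ref], category = lcat[ref])
        } else {
          presp[k] <- if (correct) "new" else "old"
          pending <- NULL
        }
        next
      }
      t_walk <- p2$choice_trial[k]
      vals <- hybrid_state_values(st)
      pers <- rep(0, 3)
      if (!is.na(st$prev)) pers[st$prev] <- ap$beta_p
      logit <- pers + ap$beta_sample * vals$v_sample + ap$beta_rl * vals$v_rl
      if (!is.null(pending)) {
        bias <- gparams$b_item * (seq_len(3) == pending$deck) +
          gparams$b_ctx * ec_mat[pending$room, ]
        if (!is.null(gist_mat) && !is.na(pending$category))
          bias <- bias + gparams$b_gist * gist_mat[pending$category, ]
        logit <- logit + bias
      }
      pr <- exp(logit - max(logit))
      pr <- pr / sum(pr)
      d <- sample.int(3L, 1L, prob = pr)
      r <- rbinom(1L, 1L, pm[d, t_walk] / 100)
      deck[k] <- d
      reward[k] <- r
      st <- hybrid_state_update(st, d, r, t_walk, ap)
      pending <- NULL
    }
  })
  out <- p2
  out$deck <- deck
  out$reward <- reward
  out$probe_response <- presp
  out
}

#' Simulate one agent through both task phases
#'
#' @inheritParams simulate_learning_phase
#' @return A full choice-dataset tibble (one row per slot, both phases).
#' @export
simulate_agent <- function(gparams, series, schedule, seed = 1L) {
  seeds <- derive_seeds(seed, 2L)
  p1 <- simulate_learning_phase(gparams, series, schedule, seeds[1])
  p2 <- simulate_probe_phase(gparams, p1, series, schedule, seeds[2])
  dplyr::bind_rows(p1, p2)
}

#' MST response model probabilities
#'
#' Three-state confusion model with a single precision parameter and fixed
#' guessing rates. Response probabilities by test condition:
#' repetitions are precision-independent (old 0.85, similar 0.10,
#' new 0.05); lures have `p(similar) = 0.10 + 0.70 * precision`,
#' `p(old) = 0.60 - 0.45 * precision`, remainder "new"; foils are fixed at
#' (old 0.10, similar 0.10, new 0.80). The expected lure discrimination
#' index is therefore `0.70 * precision` (see [expected_ldi()]), a
#' monotone function of precision.
#'
#' @param precision Latent memory precision in \[0, 1\].
#' @return A 3 x 3 matrix (conditions x responses).
#' @export
mst_response_probs <- function(precision) {
  stopifnot(precision >= 0, precision <= 1)
  m <- rbind(
    repetition = c(0.85, 0.10, 0.05),
    lure = c(0.60 - 0.45 * precision, 0.10 + 0.70 * precision,
             0.30 - 0.25 * precision),
    foil = c(0.10, 0.10, 0.80))
  colnames(m) <- c("old", "similar", "new")
  m
}

#' Expected lure discrimination index of the MST response model
#'
#' @inheritParams mst_response_probs
#' @return `0.70 * precision`, the closed-form expectation of
#'   `p(similar | lure) - p(similar | foil)` under [mst_response_probs()].
#' @export
expected_ldi <- function(precision) {
  m <- mst_response_probs(precision)
  unname(m["lure", "similar"] - m["foil", "similar"])
}

#' Simulate Mnemonic Similarity Task responses
#'
#' Emits a 128-item study list and a 192-item test list in equal thirds of
#' exact repetitions, perceptually similar lures, and novel foils, with
#' old/similar/new responses drawn from [mst_response_probs()].
#'
#' @inheritParams mst_response_probs
#' @param seed Integer seed.
#' @param n_study,n_test Study/test list lengths (`n_test` must be a
#'   multiple of 3).
#' @return An `mst_responses` list with tibbles `study` and `test`.
#' @export
simulate_mst <- function(precision, seed = 1L, n_study = 128L,
                         n_test = 192L) {
  stopifnot(n_test %% 3 == 0)
  probs <- mst_response_probs(precision)
  per <- n_test %/% 3L
  out <- withr::with_seed(seed, {
    condition <- sample(rep(rownames(probs), each = per))
    response <- vapply(condition, function(cond) {
      sample(colnames(probs), 1L, prob = probs[cond, ])
    }, character(1), USE.NAMES = FALSE)
    tibble(item = seq_len(n_test), condition = condition,
           response = response)
  })
  structure(list(study = tibble(item = seq_len(n_study)), test = out,
                 precision = precision),
            class = "mst_responses")
}

#' Cohort specification
#'
#' Defines a synthetic lifespan cohort: ages uniform over `age_range`, a
#' latent memory precision that declines with age, and a mapping from
#' (age, precision) to generative parameters encoding the directions the
#' analyses assume as ground truth: precision raises `beta_sample` and
#' probe-recognition accuracy, age lowers `beta_rl` and raises `beta_p`.
#'
#' @param n Number of agents.
#' @param variant Experiment variant, 1 or 2.
#' @param seed Master seed; the whole cohort is reproducible from it.
#' @param age_range Two-element integer range of ages.
#' @param b_item,b_ctx,b_gist Probe-bias weights shared by all agents.
#' @param walk_config A [reward_walk_config()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 100L, variant = 1, seed = 1L,
                        age_range = c(18L, 77L),
                        b_item = 0.5, b_ctx = 1, b_gist = 0,
                        walk_config = reward_walk_config()) {
  stopifnot(n >= 0, variant %in% c(1, 2), length(age_range) == 2)
  structure(list(n = as.integer(n), variant = as.integer(variant),
                 seed = as.integer(seed), age_range = as.integer(age_range),
                 b_item = b_item, b_ctx = b_ctx, b_gist = b_gist,
                 walk_config = walk_config),
            class = "cohort_spec")
}

# (age, noise) -> latent precision and generative parameters
cohort_draw_covariates <- function(spec) {
  n <- spec$n
  age <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  a <- (age - 18) / (77 - 18)
  # age explains about a third of precision variance (r ~ -0.57), leaving
  # genuine age-independent precision signal, as in lifespan MST samples
  precision <- clamp(0.78 - 0.38 * a + rnorm(n, 0, 0.16), 0, 1)
  tibble(
    agent = seq_len(n),
    age = age,
    precision = precision,
    alpha_rl = runif(n, 0.2, 0.6),
    alpha_sample = runif(n, 0.3, 0.8),
    beta_rl = clamp(7.5 - 5 * a + rnorm(n, 0, 1), 0, 20),
    beta_sample = clamp(1 + 6 * precision + rnorm(n, 0, 0.75), 0, 20),
    beta_p = clamp(-0.6 + 1.4 * a + rnorm(n, 0, 0.25), -3, 3),
    probe_recognition_accuracy = clamp(0.6 + 0.35 * precision, 0, 1))
}

#' Generate a synthetic cohort
#'
#' Draws the cohort covariates and ground-truth parameters, then simulates
#' each agent's full task (per-agent schedule and reward walk, with
#' lure-opposed payoffs in variant 2) and MST session. The ground-truth
#' table is retained for recovery scoring.
#'
#' @param spec A [cohort_spec()].
#' @return A `bandit_cohort` list: `$spec`, `$truth` (covariates and
#'   generative parameters), `$data`, `$mst`, `$schedules` (per-agent
#'   lists).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  if (n == 0) {
    return(structure(list(spec = spec, truth = cohort_draw_covariates(spec),
                          data = list(), mst = list(), schedules = list()),
                     class = "bandit_cohort"))
  }
  drawn <- withr::with_seed(spec$seed, {
    list(truth = cohort_draw_covariates(spec),
         seeds = matrix(sample.int(2147483646L, 4L * n), ncol = 4L))
  })
  truth <- drawn$truth
  seeds <- drawn$seeds

  data <- vector("list", n)
  mst <- vector("list", n)
  schedules <- vector("list", n)
  for (i in seq_len(n)) {
    schedule <- build_schedule(spec$variant, seed = seeds[i, 1])
    series <- generate_reward_walk(spec$walk_config, schedule,
                                   seed = seeds[i, 2])
    if (spec$variant == 2)
      series <- assign_lure_opposed_walks(series, schedule)
    gp <- generative_params(
      agent_params(truth$alpha_rl[i], truth$alpha_sample[i],
                   truth$beta_rl[i], truth$beta_sample[i], truth$beta_p[i]),
      b_item = spec$b_item, b_ctx = spec$b_ctx, b_gist = spec$b_gist,
      probe_recognition_accuracy = truth$probe_recognition_accuracy[i])
    data[[i]] <- simulate_agent(gp, series, schedule, seed = seeds[i, 3])
    mst[[i]] <- simulate_mst(truth$precision[i], seed = seeds[i, 4])
    schedules[[i]] <- schedule
  }
  structure(list(spec = spec, truth = truth, data = data, mst = mst,
                 schedules = schedules),
            class = "bandit_cohort")
}

#' @export
print.bandit_cohort <- function(x, ...) {
  cat(sprintf("<bandit_cohort> %d agents, experiment variant %d, seed %d\n",
              x$spec$n, x$spec$variant, x$spec$seed))
  invisible(x)
}
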