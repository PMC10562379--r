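# Hybrid choice model: temporal-difference RL and recency-weighted memory
# sampling feeding a three-term softmax policy.

#' Agent parameters for the hybrid model
#'
#' The five fitted parameters: TD learning rate `alpha_rl` in \[0, 1\],
#' sampler recency decay `alpha_sample` in \[0, 1\], inverse temperatures
#' `beta_rl` and `beta_sample` in \[0, 20\], and perseveration weight
#' `beta_p` in \[-3, 3\].
#'
#' @param alpha_rl,alpha_sample,beta_rl,beta_sample,beta_p Numeric scalars
#'   within the bounds above.
#' @return An `agent_params` list.
#' @export
agent_params <- function(alpha_rl = 0.3, alpha_sample = 0.5,
                         beta_rl = 5, beta_sample = 5, beta_p = 0) {
  b <- param_bounds()
  p <- list(alpha_rl = alpha_rl, alpha_sample = alpha_sample,
            beta_rl = beta_rl, beta_sample = beta_sample, beta_p = beta_p)
  for (i in seq_len(nrow(b))) {
    v <- p[[b$param[i]]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        v < b$lower[i] || v > b$upper[i])
      stop(sprintf("`%s` must be a single value in [%g, %g]",
                   b$param[i], b$lower[i], b$upper[i]), call. = FALSE)
  }
  structure(p, class = "agent_params")
}

#' Temporal-difference value update
#'
#' Moves the chosen deck's value toward the received reward by fraction
#' `alpha_rl`; unchosen decks are not updated.
#'
#' @param v Numeric vector of three deck values.
#' @param deck Chosen deck index (1-3).
#' @param reward Outcome, 0 or 1.
#' @param alpha_rl Learning rate in \[0, 1\].
#' @return The updated value vector.
#' @export
rl_update <- function(v, deck, reward, alpha_rl) {
  stopifnot(length(v) == 3, alpha_rl >= 0, alpha_rl <= 1)
  if (!deck %in% 1:3)
    stop("`deck` must be 1, 2 or 3", call. = FALSE)
  v[deck] <- v[deck] + alpha_rl * (reward - v[deck])
  v
}

#' Recency weights over one deck's choice history
#'
#' Evaluates the sampling kernel `alpha * (1 - alpha)^(t - i)` at each past
#' choice `i` of the deck and renormalizes it to a proper distribution over
#' that deck's history, so the sampler value is a true expectation. In the
#' `alpha_sample = 1` limit all weight falls on the most recent choice.
#'
#' @param history Data frame with columns `trial` (strictly increasing,
#'   all `< t`) and `reward` (0/1), one row per past choice of the deck.
#' @param alpha_sample Recency decay in (0, 1\].
#' @param t Current trial index.
#' @return Numeric weights summing to 1, in history order.
#' @export
sampler_weights <- function(history, alpha_sample, t) {
  i <- history$trial
  if (length(i) == 0)
    stop("sampler weights are undefined for a never-chosen deck",
         call. = FALSE)
  if (any(i >= t) || is.unsorted(i, strictly = TRUE))
    stop("`history$trial` must be strictly increasing and all < t",
         call. = FALSE)
  if (alpha_sample >= 1) {
    w <- rep(0, length(i))
    w[length(w)] <- 1
    return(w)
  }
  # relative weights; the common alpha factor cancels under normalization
  logw <- (t - i) * log1p(-alpha_sample)
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Memory-sampling value of one deck
#'
#' Expectation of the deck's past rewards under the renormalized recency
#' kernel of [sampler_weights()]. A deck that has never been chosen takes
#' the `fallback` value (0 by default, matching the RL initialization).
#'
#' @inheritParams sampler_weights
#' @param fallback Value for an empty history.
#' @return A value in \[0, 1\].
#' @export
sampler_value <- function(history, alpha_sample, t, fallback = 0) {
  if (nrow(history) == 0) return(fallback)
  sum(sampler_weights(history, alpha_sample, t) * history$reward)
}

#' Softmax choice probabilities of the hybrid policy
#'
#' Combines perseveration, sampler values and RL values into deck logits
#' `beta_p * I(x == prev) + beta_sample * V_sample(x) + beta_rl * V_rl(x)`
#' and applies a numerically stable softmax (max-logit subtraction, so
#' probabilities are invariant to constant logit shifts). On the first
#' trial, or after a missing response, `prev_choice` is `NA`/`NULL` and no
#' deck receives the perseveration term.
#'
#' @param v_rl,v_sample Numeric vectors of three deck values.
#' @param prev_choice Previously chosen deck (1-3), or `NA`/`NULL`.
#' @param params An [agent_params()] object (or compatible list).
#' @return Three probabilities summing to 1.
#' @export
choice_probabilities <- function(v_rl, v_sample, prev_choice, params) {
  stopifnot(length(v_rl) == 3, length(v_sample) == 3)
  pers <- rep(0, 3)
  if (!is.null(prev_choice) && !is.na(prev_choice))
    pers[prev_choice] <- params$beta_p
  logit <- pers + params$beta_sample * v_sample + params$beta_rl * v_rl
  e <- exp(logit - max(logit))
  e / sum(e)
}

# Extract learning-phase choice/reward vectors from a choice dataset.
learning_vectors <- function(data) {
  if ("phase" %in% names(data)) data <- data[data$phase == 1, , drop = FALSE]
  if ("trial_type" %in% names(data))
    data <- data[data$trial_type == "choice", , drop = FALSE]
  deck <- as.integer(data$deck)
  reward <- as.integer(data$reward)
  reward[is.na(reward)] <- 0L
  list(deck = deck, reward = reward)
}

#' Log-likelihood of a choice sequence under the hybrid model
#'
#' Sums `log P(chosen deck)` over learning-phase choice trials, advancing
#' the TD learner and the sampler history after each trial. Trials without
#' a recorded choice contribute nothing and advance neither learner (and
#' clear the perseveration indicator). With all three weights at zero this
#' equals `n * log(1/3)`.
#'
#' @param data A choice dataset (tibble with `deck` and `reward` columns;
#'   rows with `phase`/`trial_type` columns are filtered to learning-phase
#'   choice trials).
#' @param params An [agent_params()] object (or compatible list).
#' @return The log-likelihood (non-positive).
#' @export
sequence_log_likelihood <- function(data, params) {
  v <- learning_vectors(data)
  .hybrid_loglik_cpp(v$deck, v$reward,
                     params$alpha_rl, params$alpha_sample,
                     params$beta_rl, params$beta_sample, params$beta_p)
}

#' Per-trial choice probabilities for a recorded sequence
#'
#' Runs the same recursion as [sequence_log_likelihood()] and returns the
#' model's probability of each deck on every learning-phase choice trial.
#'
#' @inheritParams sequence_log_likelihood
#' @return A tibble with columns `trial`, `deck1`, `deck2`, `deck3`.
#' @export
trial_choice_probabilities <- function(data, params) {
  v <- learning_vectors(data)
  m <- .hybrid_trial_probs_cpp(v$deck, v$reward,
                               params$alpha_rl, params$alpha_sample,
                               params$beta_rl, params$beta_sample,
                               params$beta_p)
  tibble(trial = seq_len(nrow(m)),
         deck1 = m[, 1], deck2 = m[, 2], deck3 = m[, 3])
}
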