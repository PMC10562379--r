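# Task environment: restless three-armed bandit payoff walks, room/context
# schedules for both experiment variants, and memory-probe placement.

#' Reward-walk configuration
#'
#' Parameters of the decaying Gaussian random walk that governs each deck's
#' payout probability. Each deck `i` drifts toward its current target center
#' `theta_i` according to
#' `pi[i, t+1] = lambda * pi[i, t] + (1 - lambda) * theta_i + noise`,
#' with zero-mean Gaussian noise and reflecting bounds. Target centers are a
#' permutation of `initial_targets` and rotate on a fixed schedule so that
#' the highest-paying deck changes at every rotation point.
#'
#' @param lambda Stickiness of the walk, in (0, 1).
#' @param boost_lambda Stickiness used on the first `boost_trials` trials of
#'   each room, reinforcing that decks carry over across rooms.
#' @param noise_sd Diffusion noise SD, in payout percentage points.
#' @param lower_bound,upper_bound Reflecting bounds on payout percent.
#' @param initial_targets Three distinct target payout percents, assigned to
#'   decks at random without replacement.
#' @param boost_trials Number of room-initial trials the boost applies to.
#' @param boost_mode `"stickiness"` applies `boost_lambda` on room-initial
#'   trials; `"payout100"` instead pins the highest-center deck's payout to
#'   100 on those trials.
#' @param rotation_first_trial Trial after which the first target rotation
#'   takes effect (new centers apply from the next trial on).
#' @param rotation_period Trials between successive rotations.
#'
#' @return A `reward_walk_config` list.
#' @export
reward_walk_config <- function(lambda = 0.6, boost_lambda = 0.95, noise_sd = 8,
                               lower_bound = 5, upper_bound = 95,
                               initial_targets = c(60, 30, 10),
                               boost_trials = 3,
                               boost_mode = c("stickiness", "payout100"),
                               rotation_first_trial = 10,
                               rotation_period = 30) {
  boost_mode <- match.arg(boost_mode)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0 || lambda >= 1)
    stop("`lambda` must be a single value in (0, 1)", call. = FALSE)
  if (boost_lambda <= 0 || boost_lambda >= 1)
    stop("`boost_lambda` must be in (0, 1)", call. = FALSE)
  if (noise_sd < 0)
    stop("`noise_sd` must be non-negative", call. = FALSE)
  if (!(lower_bound >= 0 && lower_bound < upper_bound && upper_bound <= 100))
    stop("`lower_bound`/`upper_bound` must satisfy 0 <= lower < upper <= 100",
         call. = FALSE)
  if (length(initial_targets) != 3 || anyDuplicated(initial_targets) > 0)
    stop("`initial_targets` must be three distinct values", call. = FALSE)
  if (any(initial_targets < lower_bound) || any(initial_targets > upper_bound))
    stop("`initial_targets` must lie within the reflecting bounds",
         call. = FALSE)
  if (rotation_period <= 0)
    stop("`rotation_period` must be positive", call. = FALSE)
  if (rotation_first_trial < 1)
    stop("`rotation_first_trial` must be at least 1", call. = FALSE)
  structure(
    list(lambda = lambda, boost_lambda = boost_lambda, noise_sd = noise_sd,
         lower_bound = lower_bound, upper_bound = upper_bound,
         initial_targets = as.numeric(initial_targets),
         boost_trials = as.integer(boost_trials), boost_mode = boost_mode,
         rotation_first_trial = as.integer(rotation_first_trial),
         rotation_period = as.integer(rotation_period)),
    class = "reward_walk_config")
}

#' Build a task schedule
#'
#' Lays out both task phases: 180 learning trials across 6 consecutive
#' 30-trial rooms (each with its own scene context), then a probe phase of
#' 180 slots holding 120 choice trials and 60 pseudorandomly interspersed
#' memory-probe trials (50 referencing old learning trials, 10 novel).
#' Old probes are drawn only from the first ten trials of each room,
#' allocated as evenly as possible (8 or 9 per room). Probes never occupy
#' the final phase-2 slot and are never adjacent, so every probe is followed
#' by a choice trial. In variant 2 the six contexts form three perceptually
#' aliased category pairs: rooms 1-3 use one context per category, rooms 4-6
#' the category foils, and rooms 3 and 4 never share a category.
#'
#' @param variant Experiment variant, 1 or 2.
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param n_rooms,room_length Learning-phase structure.
#' @param n_phase2_choice Number of phase-2 choice trials.
#' @param n_probes_old,n_probes_novel Probe counts.
#' @param probe_source_window Within-room window (first trials of each room)
#'   from which old probes are drawn.
#'
#' @return A `bandit_schedule` object; `$trials` is a tibble with one row
#'   per slot (columns `slot`, `phase`, `trial_type`, `choice_trial`,
#'   `room`, `context_id`, `category`, `probe_kind`, `probe_ref`).
#' @export
build_schedule <- function(variant = 1, seed = 1L,
                           n_rooms = 6L, room_length = 30L,
                           n_phase2_choice = 120L,
                           n_probes_old = 50L, n_probes_novel = 10L,
                           probe_source_window = 10L) {
  if (!variant %in% c(1, 2))
    stop("`variant` must be 1 or 2", call. = FALSE)
  n_learning <- n_rooms * room_length
  n_probes <- n_probes_old + n_probes_novel
  n_slots2 <- n_phase2_choice + n_probes
  if (n_probes >= n_slots2 / 2 + 1)
    stop("too many probes for non-adjacent placement", call. = FALSE)

  out <- withr::with_seed(seed, {
    categories <- c("beach", "forest", "mountain")
    if (variant == 1) {
      context_id <- sprintf("scene%d", seq_len(n_rooms))
      category <- rep(NA_character_, n_rooms)
    } else {
      first <- sample(categories)
      repeat {
        second <- sample(categories)
        if (second[1] != first[3]) break
      }
      category <- c(first, second)
      context_id <- paste0(category, c(rep(1L, 3), rep(2L, 3)))
    }
    rooms <- tibble(room = seq_len(n_rooms), context_id = context_id,
                    category = category)

    phase1 <- tibble(
      slot = seq_len(n_learning),
      phase = 1L,
      trial_type = "choice",
      choice_trial = seq_len(n_learning),
      room = rep(seq_len(n_rooms), each = room_length))
    phase1 <- dplyr::left_join(phase1, rooms, by = "room")
    phase1$probe_kind <- NA_character_
    phase1$probe_ref <- NA_integer_

    # Non-adjacent probe slots among phase-2 slots, excluding the final
    # slot: choose n from 1..(n_slots2 - 1 - (n - 1)) and spread by offsets.
    probe_pos <- sort(sample.int(n_slots2 - 1L - (n_probes - 1L), n_probes)) +
      seq_len(n_probes) - 1L
    kind <- sample(rep(c("old", "novel"), c(n_probes_old, n_probes_novel)))

    # Old-probe references: 8 or 9 per room, from each room's first trials.
    per_room <- rep(n_probes_old %/% n_rooms, n_rooms)
    extra <- n_probes_old %% n_rooms
    if (extra > 0) {
      bump <- sample.int(n_rooms, extra)
      per_room[bump] <- per_room[bump] + 1L
    }
    refs <- unlist(lapply(seq_len(n_rooms), function(r) {
      (r - 1L) * room_length + sample.int(probe_source_window, per_room[r])
    }))
    refs <- sample(refs)

    phase2 <- tibble(
      slot = n_learning + seq_len(n_slots2),
      phase = 2L,
      trial_type = "choice",
      choice_trial = NA_integer_,
      room = NA_integer_,
      context_id = NA_character_,
      category = NA_character_,
      probe_kind = NA_character_,
      probe_ref = NA_integer_)
    phase2$trial_type[probe_pos] <- "probe"
    is_choice <- phase2$trial_type == "choice"
    phase2$choice_trial[is_choice] <- n_learning + seq_len(sum(is_choice))
    phase2$probe_kind[probe_pos] <- kind
    phase2$probe_ref[probe_pos][kind == "old"] <- refs

    list(trials = dplyr::bind_rows(phase1, phase2), rooms = rooms)
  })

  structure(
    list(variant = as.integer(variant),
         n_learning = as.integer(n_learning),
         n_rooms = as.integer(n_rooms),
         room_length = as.integer(room_length),
         n_phase2_choice = as.integer(n_phase2_choice),
         n_phase2_slots = as.integer(n_slots2),
         n_choice_trials = as.integer(n_learning + n_phase2_choice),
         n_probes_old = as.integer(n_probes_old),
         n_probes_novel = as.integer(n_probes_novel),
         probe_source_window = as.integer(probe_source_window),
         trials = out$trials,
         room_contexts = out$rooms,
         seed = as.integer(seed)),
    class = "bandit_schedule")
}

#' @export
print.bandit_schedule <- function(x, ...) {
  cat(sprintf(
    "<bandit_schedule> variant %d: %d learning trials (%d rooms x %d), %d phase-2 choice trials, %d probes (%d old / %d novel)\n",
    x$variant, x$n_learning, x$n_rooms, x$room_length, x$n_phase2_choice,
    x$n_probes_old + x$n_probes_novel, x$n_probes_old, x$n_probes_novel))
  invisible(x)
}

# Cyclic shift of the deck -> center assignment; any single or double
# application moves the highest center to a different deck.
rotate_centers <- function(a, steps = 1L) {
  for (k in seq_len(steps)) a <- a[c(2L, 3L, 1L)]
  a
}

# Per-trial center assignments (3 x n matrix). Rotations take effect after
# trial `rotation_first_trial` and every `rotation_period` trials after,
# continuing through phase 2. With `opposed = TRUE` (variant 2), rotations
# in foil rooms may take a double step so that each foil room's modal
# highest-center deck differs from its same-category partner's.
walk_center_schedule <- function(config, schedule, n_trials, init_assign,
                                 opposed = FALSE) {
  first <- config$rotation_first_trial
  period <- config$rotation_period
  rot_trials <- if (first + 1L > n_trials) integer(0) else
    seq(first + 1L, n_trials, by = period)

  partner_modal <- NULL
  if (opposed) {
    rc <- schedule$room_contexts
    partner_of <- function(r) {
      rc$room[rc$category == rc$category[rc$room == r] & rc$room != r]
    }
    # modal assignment of room k is the one set at rotation k (active for
    # its last `period - first` trials)
    partner_modal <- lapply(seq_len(schedule$n_rooms), partner_of)
  }

  centers <- matrix(0, nrow = 3, ncol = n_trials)
  assign <- init_assign
  modal_by_rotation <- list()  # assignment in force after rotation j
  j <- 0L
  for (t in seq_len(n_trials)) {
    if (j < length(rot_trials) && t == rot_trials[j + 1L]) {
      j <- j + 1L
      cand <- rotate_centers(assign, 1L)
      if (opposed && j >= 4L && j <= schedule$n_rooms) {
        partner <- partner_modal[[j]]
        partner_assign <- modal_by_rotation[[partner]]
        if (which.max(cand) == which.max(partner_assign))
          cand <- rotate_centers(assign, 2L)
      }
      assign <- cand
      modal_by_rotation[[j]] <- assign
    }
    centers[, t] <- assign
  }
  centers
}

#' One deterministic-plus-noise step of the payout walk
#'
#' `lambda * payout + (1 - lambda) * center + noise`, reflected into the
#' bounds. With zero noise and `payout == center` the walk is at its fixed
#' point.
#'
#' @param payout Current payout value(s), percent.
#' @param center Target center(s) the walk decays toward.
#' @param lambda Stickiness in (0, 1).
#' @param noise Additive noise value(s) (default 0).
#' @param lower,upper Reflecting bounds.
#' @return The next payout value(s).
#' @export
walk_step <- function(payout, center, lambda, noise = 0,
                      lower = 5, upper = 95) {
  x <- lambda * payout + (1 - lambda) * center + noise
  while (any(x < lower | x > upper)) {
    x <- ifelse(x > upper, 2 * upper - x, x)
    x <- ifelse(x < lower, 2 * lower - x, x)
  }
  x
}

#' Generate reward-walk payout trajectories
#'
#' Realizes per-deck payout probabilities over all choice trials of a
#' schedule (phase 1 and 2; the walk continues through the probe phase)
#' according to the decaying Gaussian random walk in
#' [reward_walk_config()], with reflecting bounds, room-initial stickiness
#' boost, and rotating target centers. Rotation is a cyclic permutation of
#' the three centers, so the new highest-paying deck always differs from
#' the previous one.
#'
#' @param config A [reward_walk_config()].
#' @param schedule A [build_schedule()] object.
#' @param seed Integer seed; identical `(config, schedule, seed)` give
#'   bit-identical series.
#' @param n_trials Optional override of the number of walk trials (defaults
#'   to the schedule's total choice-trial count); useful for long-run
#'   diagnostics of the walk itself.
#' @param opposed Internal switch used by [assign_lure_opposed_walks()].
#'
#' @return A `reward_series` tibble with columns `trial`, `deck`, `payout`,
#'   `center` and one row per deck and trial.
#' @export
generate_reward_walk <- function(config, schedule, seed = 1L,
                                 n_trials = NULL, opposed = FALSE) {
  stopifnot(inherits(config, "reward_walk_config"),
            inherits(schedule, "bandit_schedule"))
  if (opposed && schedule$variant != 2)
    stop("opposed payoff walks require an experiment variant 2 schedule",
         call. = FALSE)
  n_trials <- as.integer(n_trials %||% schedule$n_choice_trials)
  if (n_trials < 1) stop("`n_trials` must be positive", call. = FALSE)

  res <- withr::with_seed(seed, {
    init_assign <- config$initial_targets[sample.int(3L)]
    noise <- matrix(rnorm(3L * n_trials, 0, config$noise_sd), nrow = 3L)
    list(init_assign = init_assign, noise = noise)
  })
  centers <- walk_center_schedule(config, schedule, n_trials,
                                  res$init_assign, opposed = opposed)

  in_boost <- function(t) {
    t <= schedule$n_learning &&
      ((t - 1L) %% schedule$room_length) + 1L <= config$boost_trials
  }

  payout <- matrix(0, nrow = 3L, ncol = n_trials)
  payout[, 1L] <- centers[, 1L]
  for (t in seq_len(n_trials)[-1]) {
    lam <- if (in_boost(t)) config$boost_lambda else config$lambda
    payout[, t] <- walk_step(payout[, t - 1L], centers[, t], lam,
                             res$noise[, t], config$lower_bound,
                             config$upper_bound)
  }
  if (config$boost_mode == "payout100") {
    for (t in seq_len(n_trials)) {
      if (in_boost(t)) payout[which.max(centers[, t]), t] <- 100
    }
  }

  out <- tibble(
    trial = rep(seq_len(n_trials), each = 3L),
    deck = rep(1:3, times = n_trials),
    payout = as.vector(payout),
    center = as.vector(centers))
  structure(out,
            class = c("reward_series", class(out)),
            walk_config = config, walk_seed = as.integer(seed),
            n_trials = n_trials, opposed = opposed,
            variant = schedule$variant)
}

#' Re-realize a variant 2 walk with lure-opposed payoffs
#'
#' In experiment variant 2, each room's reward distribution must be
#' dissociable from its same-category foil: the modal highest-center deck
#' in a foil room (rooms 4-6) must differ from that of its partner room.
#' A purely cyclic rotation schedule leaves rooms `k` and `k + 3` with
#' identical modal assignments (a 3-cycle applied three times is the
#' identity), so this regenerates the series with the same seed and noise
#' draws but with double rotation steps inserted where needed.
#'
#' @param series A `reward_series` from [generate_reward_walk()].
#' @param schedule The matching variant 2 [build_schedule()] object.
#' @return A `reward_series` satisfying the opposition constraint.
#' @export
assign_lure_opposed_walks <- function(series, schedule) {
  stopifnot(inherits(series, "reward_series"),
            inherits(schedule, "bandit_schedule"))
  if (schedule$variant != 2)
    stop("lure-opposed walks are only defined for experiment variant 2",
         call. = FALSE)
  generate_reward_walk(attr(series, "walk_config"), schedule,
                       seed = attr(series, "walk_seed"),
                       n_trials = attr(series, "n_trials"),
                       opposed = TRUE)
}

#' Payout (or center) matrix of a reward series
#'
#' @param series A `reward_series`.
#' @param what `"payout"` or `"center"`.
#' @return A 3 x n_trials numeric matrix (decks in rows).
#' @export
payout_matrix <- function(series, what = c("payout", "center")) {
  what <- match.arg(what)
  n <- attr(series, "n_trials")
  matrix(series[[what]], nrow = 3L, ncol = n)
}

#' Simulate a complete task environment
#'
#' Convenience wrapper building a schedule and its reward walk (with
#' lure-opposed payoffs applied automatically for variant 2).
#'
#' @param variant Experiment variant, 1 or 2.
#' @param seed Integer seed.
#' @param walk_config A [reward_walk_config()].
#' @return A list with elements `schedule` and `series`.
#' @export
simulate_task <- function(variant = 1, seed = 1L,
                          walk_config = reward_walk_config()) {
  seeds <- derive_seeds(seed, 2L)
  schedule <- build_schedule(variant, seed = seeds[1])
  series <- generate_reward_walk(walk_config, schedule, seed = seeds[2])
  if (variant == 2) series <- assign_lure_opposed_walks(series, schedule)
  list(schedule = schedule, series = series)
}

# Modal highest-center deck of each room (the assignment in force for the
# bulk of the room's trials).
modal_highest_deck <- function(series, schedule) {
  cm <- payout_matrix(series, "center")
  vapply(seq_len(schedule$n_rooms), function(r) {
    cols <- ((r - 1L) * schedule$room_length + 1L):(r * schedule$room_length)
    best <- apply(cm[, cols, drop = FALSE], 2, which.max)
    as.integer(names(which.max(table(best))))
  }, integer(1))
}
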