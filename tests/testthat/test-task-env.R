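# Task environment: payoff walks, schedules, probe placement, lure
# opposition.

test_that("walk configuration rejects invalid fields by name", {
  expect_error(reward_walk_config(lambda = 1.2), "lambda")
  expect_error(reward_walk_config(lower_bound = 50, upper_bound = 40),
               "lower_bound")
  expect_error(reward_walk_config(initial_targets = c(60, 60, 10)),
               "initial_targets")
  expect_error(reward_walk_config(rotation_period = 0), "rotation_period")
  expect_error(reward_walk_config(noise_sd = -1), "noise_sd")
})

test_that("zero-noise walk sits at its fixed point between rotations", {
  cfg <- reward_walk_config(noise_sd = 0, rotation_first_trial = 10000L)
  sch <- build_schedule(1, seed = 3)
  ser <- generate_reward_walk(cfg, sch, seed = 4)
  pm <- payout_matrix(ser)
  cm <- payout_matrix(ser, "center")
  # boost trials change lambda, not the fixed point, so payout == center
  expect_equal(pm, cm, tolerance = 1e-12)
})

test_that("one walk step matches the hand-evaluated decay rule", {
  expect_equal(walk_step(90, 60, 0.6), 0.6 * 90 + 0.4 * 60) # 78
  expect_equal(walk_step(50, 50, 0.6), 50)
  # reflection at the bounds
  expect_equal(walk_step(90, 90, 0.9, noise = 10), 2 * 95 - 100)
  expect_equal(walk_step(10, 10, 0.9, noise = -10), 2 * 5 - 0)
})

test_that("zero-noise rotations follow the decay toward the new center", {
  cfg <- reward_walk_config(noise_sd = 0)
  sch <- build_schedule(1, seed = 5)
  ser <- generate_reward_walk(cfg, sch, seed = 6)
  pm <- payout_matrix(ser)
  cm <- payout_matrix(ser, "center")
  boost <- unlist(lapply(0:5, function(r) r * 30 + 1:3))
  for (t in 2:300) {
    lam <- if (t %in% boost) 0.95 else 0.6
    expect_equal(pm[, t], walk_step(pm[, t - 1], cm[, t], lam),
                 tolerance = 1e-12)
  }
})

test_that("payouts respect the reflecting bounds over long runs", {
  sch <- build_schedule(1, seed = 11)
  ser <- generate_reward_walk(reward_walk_config(), sch, seed = 12,
                              n_trials = 10000)
  expect_gte(min(ser$payout), 5)
  expect_lte(max(ser$payout), 95)
})

test_that("long-run payout means sit near the centers, with a bounded
           reflection bias at the deck nearest the lower bound", {
  cfg <- reward_walk_config(rotation_first_trial = 100000L)
  sch <- build_schedule(1, seed = 21)
  ser <- generate_reward_walk(cfg, sch, seed = 22, n_trials = 5000)
  pm <- payout_matrix(ser)
  theta <- payout_matrix(ser, "center")[, 1]
  for (d in 1:3) {
    m <- mean(pm[d, -(1:100)])
    if (theta[d] >= 30) {
      expect_lt(abs(m - theta[d]), 3)
    } else {
      # reflection at the bound 5 inflates the mean of the theta = 10 deck
      expect_gte(m, theta[d])
      expect_lt(m, theta[d] + 6)
    }
  }
})

test_that("centers stay a permutation of the targets and the top deck
           changes at every rotation", {
  sch <- build_schedule(1, seed = 31)
  ser <- generate_reward_walk(reward_walk_config(), sch, seed = 32)
  cm <- payout_matrix(ser, "center")
  expect_true(all(apply(cm, 2, sort) == c(10, 30, 60)))
  am <- apply(cm, 2, which.max)
  rot <- seq(11, 300, by = 30)
  expect_true(all(am[rot] != am[rot - 1]))
  expect_true(all(diff(am)[-(rot - 1)] == 0))
})

test_that("payout100 boost mode pins the highest deck on room-start trials", {
  cfg <- reward_walk_config(boost_mode = "payout100")
  sch <- build_schedule(1, seed = 41)
  ser <- generate_reward_walk(cfg, sch, seed = 42)
  pm <- payout_matrix(ser)
  cm <- payout_matrix(ser, "center")
  boost <- unlist(lapply(0:5, function(r) r * 30 + 1:3))
  for (t in boost) expect_equal(pm[which.max(cm[, t]), t], 100)
  expect_lte(max(pm[, -boost]), 95)
})

test_that("schedules and walks are bit-identical under a fixed seed", {
  s1 <- build_schedule(2, seed = 99)
  s2 <- build_schedule(2, seed = 99)
  expect_identical(s1, s2)
  w1 <- generate_reward_walk(reward_walk_config(), s1, seed = 7)
  w2 <- generate_reward_walk(reward_walk_config(), s2, seed = 7)
  expect_identical(w1, w2)
})

test_that("default schedule has the stated structure", {
  for (variant in 1:2) {
    sch <- build_schedule(variant, seed = 13)
    tr <- sch$trials
    expect_equal(sum(tr$phase == 1), 180)
    expect_equal(length(unique(tr$context_id[tr$phase == 1])), 6)
    expect_equal(sum(tr$phase == 2 & tr$trial_type == "choice"), 120)
    expect_equal(sum(tr$trial_type == "probe"), 60)
    expect_equal(sum(tr$probe_kind == "old", na.rm = TRUE), 50)
    expect_equal(sum(tr$probe_kind == "novel", na.rm = TRUE), 10)
    expect_equal(as.vector(table(tr$room[tr$phase == 1])), rep(30L, 6))
  }
})

test_that("probes are non-adjacent, never last, and sourced from each
           room's first ten trials, 8 or 9 per room", {
  for (seed in c(1, 17, 23)) {
    sch <- build_schedule(1, seed = seed)
    tr <- sch$trials
    pp <- which(tr$trial_type == "probe")
    expect_true(all(diff(pp) >= 2))
    expect_lt(max(pp), nrow(tr))
    # every probe is followed by a choice trial
    expect_true(all(tr$trial_type[pp + 1] == "choice"))
    refs <- tr$probe_ref[!is.na(tr$probe_ref)]
    expect_equal(length(refs), 50)
    expect_true(all(((refs - 1) %% 30) < 10))
    per_room <- table(((refs - 1) %/% 30) + 1)
    expect_true(all(per_room %in% c(8, 9)))
    expect_equal(length(per_room), 6)
  }
})

test_that("variant 2 contexts form category pairs with rooms 3 and 4
           never sharing a category", {
  for (seed in 1:12) {
    sch <- build_schedule(2, seed = seed)
    rc <- sch$room_contexts
    expect_equal(sort(table(rc$category)), sort(c(2L, 2L, 2L)),
                 ignore_attr = TRUE)
    # first three rooms cover all categories; rooms 4-6 are the foils
    expect_equal(sort(unique(rc$category[1:3])), sort(unique(rc$category)))
    expect_false(rc$category[3] == rc$category[4])
  }
})

test_that("lure opposition flips the modal top deck within every
           category pair", {
  for (seed in c(2, 9, 33)) {
    sch <- build_schedule(2, seed = seed)
    ser <- generate_reward_walk(reward_walk_config(), sch, seed = seed + 1)
    opp <- assign_lure_opposed_walks(ser, sch)
    md <- membandit:::modal_highest_deck(opp, sch)
    rc <- sch$room_contexts
    for (cat in unique(rc$category)) {
      rooms <- rc$room[rc$category == cat]
      expect_false(md[rooms[1]] == md[rooms[2]])
    }
  }
})

test_that("lure opposition rejects variant 1 input and holds on
           zero-noise centers", {
  sch1 <- build_schedule(1, seed = 4)
  ser1 <- generate_reward_walk(reward_walk_config(), sch1, seed = 5)
  expect_error(assign_lure_opposed_walks(ser1, sch1), "variant 2")

  sch2 <- build_schedule(2, seed = 4)
  cfg <- reward_walk_config(noise_sd = 0)
  opp <- assign_lure_opposed_walks(
    generate_reward_walk(cfg, sch2, seed = 5), sch2)
  md <- membandit:::modal_highest_deck(opp, sch2)
  rc <- sch2$room_contexts
  for (cat in unique(rc$category)) {
    rooms <- rc$room[rc$category == cat]
    expect_false(md[rooms[1]] == md[rooms[2]])
  }
})
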