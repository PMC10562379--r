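# Probe-triggered memory-intrusion regression: evoked-context-reward
# regressors, the stacked three-deck logistic design matrix, serial
# Gram-Schmidt orthogonalization of the gist regressor, and the
# population-level tests.

#' Evoked context reward of a deck in a room
#'
#' Net win rate of a deck within a learning-phase room:
#' `(wins - losses) / times chosen`, in \[-1, 1\]. A deck never chosen in
#' the room takes 0, the uninformative midpoint.
#'
#' @param learning_data A choice dataset containing learning-phase rows.
#' @param room Room id.
#' @param deck Deck index (1-3).
#' @return The evoked context reward.
#' @export
evoked_context_reward <- function(learning_data, room, deck) {
  if (!deck %in% 1:3)
    stop("`deck` must be 1, 2 or 3", call. = FALSE)
  d <- learning_data
  if ("phase" %in% names(d)) d <- d[d$phase == 1, , drop = FALSE]
  if (!room %in% d$room)
    stop(sprintf("room %s has no learning-phase trials", room),
         call. = FALSE)
  rows <- d[d$room == room & !is.na(d$deck) & d$deck == deck, , drop = FALSE]
  n <- nrow(rows)
  if (n == 0) return(0)
  wins <- sum(rows$reward == 1)
  (2 * wins - n) / n
}

# Evoked context reward for every (room, deck) cell, rooms x decks order.
evoked_context_table <- function(learning_data) {
  d <- learning_data
  if ("phase" %in% names(d)) d <- d[d$phase == 1, , drop = FALSE]
  rooms <- sort(unique(d$room))
  tidyr::expand_grid(room = rooms, deck = 1:3) |>
    dplyr::rowwise() |>
    dplyr::mutate(ec = evoked_context_reward(d, .data$room, .data$deck)) |>
    dplyr::ungroup()
}

# Gist-level evoked reward: counts pooled over each category's room pair.
evoked_gist_table <- function(learning_data, schedule) {
  stopifnot(schedule$variant == 2)
  d <- learning_data
  if ("phase" %in% names(d)) d <- d[d$phase == 1, , drop = FALSE]
  cats <- unique(schedule$room_contexts$category)
  tidyr::expand_grid(category = cats, deck = 1:3) |>
    dplyr::rowwise() |>
    dplyr::mutate(ec_gist = {
      rows <- d[d$category == .data$category & !is.na(d$deck) &
                  d$deck == .data$deck, , drop = FALSE]
      n <- nrow(rows)
      if (n == 0) 0 else (2 * sum(rows$reward == 1) - n) / n
    }) |>
    dplyr::ungroup()
}

#' Serial Gram-Schmidt orthogonalization
#'
#' Removes from `gist` its projection onto `target`: no mean-centering,
#' no rescaling of the target column. With a zero-norm target the gist
#' column is returned unchanged, with a warning.
#'
#' @param target,gist Numeric vectors of equal length.
#' @return The orthogonalized gist vector.
#' @export
orthogonalize_serial <- function(target, gist) {
  stopifnot(length(target) == length(gist))
  nt <- sum(target^2)
  if (nt == 0) {
    warning("target column has zero norm; gist column returned unchanged")
    return(gist)
  }
  gist - target * (sum(target * gist) / nt)
}

#' Build the probe-intrusion design matrix
#'
#' Stacks one row per (deck, phase-2 choice trial): response `chosen`
#' (1 if that deck was picked) and regressors `di` (previous-trial deck
#' identity), `dr1`-`dr3` (deck chosen and rewarded at lags 1-3, lags
#' crossing the phase boundary drawing on late learning trials), and the
#' probe terms `ei` (probed deck identity), `er` (probed deck and
#' rewarded), `ec` (evoked context reward of the probed room), which are
#' nonzero only on the choice trial immediately following an old-item
#' probe. With `include_gist`, an eighth column holds the evoked reward
#' pooled over the probed room and its same-category foil, serially
#' orthogonalized against the `ec` column. Choice trials without a
#' recorded response contribute no rows. The default schedule yields
#' 360 rows and 7 regressor columns (8 with gist).
#'
#' @param dataset A full choice dataset (both phases).
#' @param schedule The matching [build_schedule()] object.
#' @param include_gist Add the orthogonalized gist column (variant 2).
#' @return A `probe_design` tibble.
#' @export
build_design_matrix <- function(dataset, schedule, include_gist = FALSE) {
  if (include_gist && schedule$variant != 2)
    stop("the gist regressor requires an experiment variant 2 schedule",
         call. = FALSE)
  ch <- dataset[dataset$trial_type == "choice", , drop = FALSE]
  ch <- ch[order(ch$choice_trial), , drop = FALSE]
  n_ct <- nrow(ch)
  chk <- as.integer(ch$deck)
  rwd <- as.integer(ch$reward)

  ec_tab <- evoked_context_table(dataset)
  ec_mat <- matrix(ec_tab$ec, nrow = length(unique(ec_tab$room)),
                   byrow = TRUE)
  gist_mat <- NULL
  cat_of_room <- NULL
  if (include_gist) {
    gt <- evoked_gist_table(dataset, schedule)
    cats <- unique(gt$category)
    gist_mat <- matrix(gt$ec_gist, nrow = length(cats), byrow = TRUE,
                       dimnames = list(cats, NULL))
    cat_of_room <- schedule$room_contexts$category[
      order(schedule$room_contexts$room)]
  }

  # map each phase-2 choice trial to the old probe (if any) on the
  # immediately preceding slot
  tr <- dataset[dataset$phase == 2, , drop = FALSE]
  tr <- tr[order(tr$slot), , drop = FALSE]
  probe_for <- rep(NA_integer_, n_ct)  # choice trial -> probed learning trial
  prev_probe_ref <- NA_integer_
  for (k in seq_len(nrow(tr))) {
    if (tr$trial_type[k] == "probe") {
      prev_probe_ref <- if (tr$probe_kind[k] == "old") tr$probe_ref[k] else
        NA_integer_
    } else {
      probe_for[tr$choice_trial[k]] <- prev_probe_ref
      prev_probe_ref <- NA_integer_
    }
  }

  p2_ct <- (schedule$n_learning + 1L):n_ct
  p2_ct <- p2_ct[!is.na(chk[p2_ct])]  # missing responses: no rows
  ref <- probe_for[p2_ct]
  bad <- !is.na(ref) & (ref < 1 | ref > schedule$n_learning)
  if (any(bad))
    stop(sprintf("probe reference %d does not resolve to a learning trial",
                 ref[which(bad)[1]]), call. = FALSE)
  probed_deck <- ifelse(is.na(ref), NA_integer_, chk[ref])
  probed_rwd <- ifelse(is.na(ref), NA_integer_, rwd[ref])
  probed_room <- ifelse(is.na(ref), NA_integer_,
                        ((ref - 1L) %/% schedule$room_length) + 1L)
  # probed trial with a missing response carries no probe information
  no_info <- !is.na(ref) & is.na(probed_deck)
  probed_deck[no_info] <- NA_integer_

  blocks <- lapply(1:3, function(i) {
    di <- as.integer(!is.na(chk[p2_ct - 1L]) & chk[p2_ct - 1L] == i)
    drs <- lapply(1:3, function(k) {
      idx <- p2_ct - k
      as.integer(idx >= 1 & !is.na(chk[idx]) & chk[idx] == i &
                   !is.na(rwd[idx]) & rwd[idx] == 1L)
    })
    ei <- as.integer(!is.na(probed_deck) & probed_deck == i)
    er <- as.integer(ei == 1L & !is.na(probed_rwd) & probed_rwd == 1L)
    okp <- !is.na(probed_deck)
    ec <- numeric(length(probed_deck))
    ec[okp] <- ec_mat[cbind(probed_room[okp], i)]
    out <- tibble(
      choice_trial = p2_ct, deck = i,
      chosen = as.integer(chk[p2_ct] == i),
      di = di, dr1 = drs[[1]], dr2 = drs[[2]], dr3 = drs[[3]],
      ei = ei, er = er, ec = ec)
    if (include_gist) {
      gr <- numeric(length(probed_deck))
      cat_idx <- match(cat_of_room[probed_room[okp]], rownames(gist_mat))
      gr[okp] <- gist_mat[cbind(cat_idx, i)]
      out$ec_gist_raw <- gr
    }
    out
  })
  dm <- dplyr::arrange(dplyr::bind_rows(blocks), .data$choice_trial,
                       .data$deck)
  if (include_gist) {
    dm$ec_gist <- orthogonalize_serial(dm$ec, dm$ec_gist_raw)
    dm$ec_gist_raw <- NULL
  }
  structure(dm, class = c("probe_design", class(dm)),
            include_gist = include_gist)
}

probe_regressors <- function(dm) {
  c("di", "dr1", "dr2", "dr3", "ei", "er", "ec",
    if (isTRUE(attr(dm, "include_gist"))) "ec_gist")
}

#' Fit the probe-intrusion logistic regression
#'
#' Maximum-likelihood logistic fit of the stacked design matrix with
#' coefficients shared across the three deck parts (plus an intercept,
#' which is not reported among the named regressors). Coefficients are log
#' relative choice odds. If the fit shows separation (fitted probabilities
#' pinned at 0/1 or non-convergence), a weakly ridge-penalized fit is
#' substituted and flagged. `per_deck = TRUE` instead fits each deck's
#' part separately.
#'
#' @param dm A `probe_design` from [build_design_matrix()].
#' @param per_deck Fit the three deck parts separately.
#' @return A `probe_regression` object (coefficients tibble, convergence
#'   and separation flags, fit method).
#' @export
fit_probe_regression <- function(dm, per_deck = FALSE) {
  stopifnot(inherits(dm, "probe_design"))
  if (nrow(dm) == 0 || all(dm$chosen == 0))
    stop("design matrix is empty or has an all-zero response",
         call. = FALSE)
  terms <- probe_regressors(dm)
  if (per_deck) {
    coefs <- purrr::map_dfr(1:3, function(i) {
      sub <- dm[dm$deck == i, , drop = FALSE]
      fit <- fit_stacked_logistic(sub, terms)
      dplyr::mutate(fit$coefficients, deck = i)
    })
    return(structure(list(coefficients = coefs, per_deck = TRUE,
                          n = nrow(dm)),
                     class = "probe_regression"))
  }
  fit <- fit_stacked_logistic(dm, terms)
  structure(list(coefficients = fit$coefficients, converged = fit$converged,
                 separated = fit$separated, method = fit$method,
                 per_deck = FALSE, n = nrow(dm)),
            class = "probe_regression")
}

fit_stacked_logistic <- function(dm, terms) {
  fml <- stats::as.formula(paste("chosen ~", paste(terms, collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dm),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  method <- "glm"
  cf <- coef(fit)
  if (separated || !fit$converged || anyNA(cf)) {
    # weakly penalized fallback: ridge logistic with a small penalty;
    # constant columns carry no information and keep a zero coefficient
    x <- as.matrix(dm[terms])
    keep <- apply(x, 2, function(v) stats::var(v) > 0)
    cf <- setNames(rep(0, length(terms) + 1L), c("(Intercept)", terms))
    if (any(keep)) {
      if (sum(keep) == 1L) {
        # glmnet needs >= 2 columns; pad with a dummy that stays at zero
        x2 <- cbind(x[, keep, drop = FALSE], .dummy = 0)
        rg <- glmnet::glmnet(x2, dm$chosen, family = "binomial", alpha = 0,
                             lambda = 1e-3, standardize = FALSE,
                             exclude = 2L)
        cf[colnames(x)[keep]] <- as.numeric(rg$beta)[1]
      } else {
        rg <- glmnet::glmnet(x[, keep, drop = FALSE], dm$chosen,
                             family = "binomial", alpha = 0,
                             lambda = 1e-3, standardize = FALSE)
        cf[rownames(rg$beta)] <- as.numeric(rg$beta)
      }
      cf["(Intercept)"] <- as.numeric(rg$a0)
    } else {
      cf["(Intercept)"] <- qlogis(mean(dm$chosen))
    }
    method <- "ridge"
    separated <- TRUE
  }
  list(coefficients = tibble(term = c("(Intercept)", terms),
                             estimate = unname(cf[c("(Intercept)", terms)])),
       converged = method == "glm", separated = separated, method = method)
}

#' @export
print.probe_regression <- function(x, ...) {
  cat("<probe_regression>",
      if (isTRUE(x$per_deck)) "per-deck fits" else x$method,
      "on", x$n, "rows\n")
  print(x$coefficients)
  invisible(x)
}

#' Population-level test of a regression coefficient
#'
#' Two-tailed one-sample t-test of per-participant coefficient estimates
#' against zero.
#'
#' @param values Numeric vector of per-participant estimates (length >= 2,
#'   non-zero variance).
#' @return A one-row tibble: `estimate` (mean), `statistic`, `df`,
#'   `p_value`, `n`.
#' @export
population_test <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("population test needs at least 2 values", call. = FALSE)
  if (sd(values) == 0)
    stop("population test is undefined for zero-variance values",
         call. = FALSE)
  tt <- t.test(values)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         n = length(values))
}

#' Probe-intrusion regression across a cohort
#'
#' Builds each agent's design matrix, fits the stacked logistic
#' regression, and tests each regressor's per-agent coefficients against
#' zero across the population.
#'
#' @param cohort A `bandit_cohort`.
#' @param include_gist Include the orthogonalized gist column.
#' @param agents Optional subset of agent indices.
#' @return A list with `coefficients` (per agent x term) and `population`
#'   (one row per term: mean, t, p).
#' @export
regress_cohort <- function(cohort, include_gist = FALSE, agents = NULL) {
  stopifnot(inherits(cohort, "bandit_cohort"))
  agents <- agents %||% seq_along(cohort$data)
  coefs <- purrr::map_dfr(agents, function(i) {
    dm <- build_design_matrix(cohort$data[[i]], cohort$schedules[[i]],
                              include_gist = include_gist)
    fit <- fit_probe_regression(dm)
    dplyr::mutate(fit$coefficients, agent = i,
                  separated = isTRUE(fit$separated))
  })
  pop <- coefs |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(population_test(.data$estimate), .groups = "drop")
  list(coefficients = coefs, population = pop)
}
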