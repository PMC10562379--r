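# Mnemonic Similarity Task scoring: the lure discrimination index.

#' Lure discrimination index (LDI)
#'
#' Scores MST test responses into
#' `LDI = p("similar" | lure) - p("similar" | foil)`, the standard index
#' of mnemonic discrimination (higher = more precise memory). Conditional
#' proportions are computed over responded trials of each condition;
#' trials without a response are excluded from the denominators. The
#' index lies in \[-1, 1\] and is invariant to repetition-condition
#' responses.
#'
#' @param responses An `mst_responses` object from [simulate_mst()], or a
#'   tibble with columns `condition` (`"repetition"`, `"lure"`, `"foil"`)
#'   and `response` (`"old"`, `"similar"`, `"new"`, or `NA`).
#' @return An `mst_summary` one-row tibble with `p_similar_lure`,
#'   `p_similar_foil`, `ldi`, and the per-condition response counts; the
#'   full 3 x 3 count table is attached as attribute `"counts"`.
#' @export
compute_ldi <- function(responses) {
  test <- if (inherits(responses, "mst_responses")) responses$test else
    responses
  stopifnot(all(c("condition", "response") %in% names(test)))
  resp <- test[!is.na(test$response), , drop = FALSE]
  n_lure <- sum(resp$condition == "lure")
  n_foil <- sum(resp$condition == "foil")
  if (n_lure == 0 || n_foil == 0)
    stop("LDI requires at least one responded lure and one responded foil trial",
         call. = FALSE)
  p_sim_lure <- mean(resp$response[resp$condition == "lure"] == "similar")
  p_sim_foil <- mean(resp$response[resp$condition == "foil"] == "similar")
  counts <- resp |>
    dplyr::count(.data$condition, .data$response) |>
    tidyr::complete(
      condition = c("repetition", "lure", "foil"),
      response = c("old", "similar", "new"),
      fill = list(n = 0L))
  out <- tibble(n_lure = n_lure, n_foil = n_foil,
                p_similar_lure = p_sim_lure, p_similar_foil = p_sim_foil,
                ldi = p_sim_lure - p_sim_foil)
  structure(out, class = c("mst_summary", class(out)), counts = counts)
}

#' Score every MST session of a cohort
#'
#' @param cohort A `bandit_cohort`.
#' @return A tibble with one row per agent: `agent`, `ldi`,
#'   `p_similar_lure`, `p_similar_foil`.
#' @export
score_mst_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "bandit_cohort"))
  purrr::map_dfr(seq_along(cohort$mst), function(i) {
    s <- compute_ldi(cohort$mst[[i]])
    tibble(agent = i, ldi = s$ldi, p_similar_lure = s$p_similar_lure,
           p_similar_foil = s$p_similar_foil)
  })
}
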