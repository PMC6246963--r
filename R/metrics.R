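#' Per-response error metrics
#'
#' For each response, with estimate \eqn{\hat c} and ground truth \eqn{c}:
#' error \eqn{e = \hat c - c} (kcal, positive = overestimate), percent error
#' \eqn{\eta = e / c} (stored as a fraction, not a percentage), absolute
#' error \eqn{|e|}, and the correctness flag `correct20` = \eqn{|\eta| \le
#' 0.20} ("within 20% of truth", boundary inclusive — centralized in one
#' internal constant).
#'
#' @param responses Response tibble (`participant_id`, `food_id`,
#'   `estimate_kcal`).
#' @param quiz A `quiz_spec` supplying ground truth.
#' @return A tibble with `participant_id`, `food_id`, `estimate_kcal`,
#'   `truth_kcal`, `e`, `eta`, `abs_e`, `correct20`.
#' @export
#' @examples
#' quiz <- load_quiz("table1")
#' r <- tibble::tibble(participant_id = "P1", food_id = "potato",
#'                     estimate_kcal = 150)
#' compute_metrics(r, quiz)  # e = 50, eta = 0.5, correct20 FALSE
compute_metrics <- function(responses, quiz) {
  assert_columns(responses, c("participant_id", "food_id", "estimate_kcal"),
                 "responses")
  unknown <- setdiff(responses$food_id, quiz$food_id)
  if (length(unknown) > 0) {
    abort(sprintf("responses reference food_id(s) not in the quiz: %s",
                  paste(unknown, collapse = ", ")))
  }
  responses %>%
    dplyr::inner_join(
      tibble::as_tibble(quiz)[, c("food_id", "energy_kcal")],
      by = "food_id"
    ) %>%
    dplyr::rename(truth_kcal = "energy_kcal") %>%
    dplyr::mutate(
      e = .data$estimate_kcal - .data$truth_kcal,
      eta = .data$e / .data$truth_kcal,
      abs_e = abs(.data$e),
      correct20 = abs(.data$eta) <= CORRECT_TOL
    )
}

#' Per-participant accuracy summary (discrete accuracy D)
#'
#' Discrete accuracy `D` is the number of a participant's estimates within
#' 20% of the true calorie value — the feedback measure shown to quiz takers,
#' out of 20 answers in the original quiz. Incomplete participants get the
#' count over their answered items, with `n_answered` reported alongside.
#'
#' @param metrics Metric tibble from [compute_metrics()].
#' @return One row per participant: `D`, `n_answered`, `mean_abs_e_kcal`,
#'   `mean_abs_eta`.
#' @export
participant_summary <- function(metrics) {
  metrics %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::summarise(
      D = sum(.data$correct20),
      n_answered = dplyr::n(),
      mean_abs_e_kcal = mean(.data$abs_e),
      mean_abs_eta = mean(abs(.data$eta)),
      .groups = "drop"
    )
}

#' Per-food metric summary
#'
#' One row per quiz food: response count, mean and median of `e`, `eta` and
#' `abs_e`, and the 25/50/75% quantiles of the raw estimates (the tabular
#' content behind a violin/box display of per-food estimate distributions).
#' Foods with no responses appear with `n = 0` and missing statistics.
#'
#' @inheritParams compute_metrics
#' @param metrics Metric tibble from [compute_metrics()].
#' @return A tibble with one row per food in quiz order.
#' @export
per_food_summary <- function(metrics, quiz) {
  stats_tbl <- metrics %>%
    dplyr::group_by(.data$food_id) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_e = mean(.data$e), median_e = stats::median(.data$e),
      mean_eta = mean(.data$eta), median_eta = stats::median(.data$eta),
      mean_abs_e = mean(.data$abs_e), median_abs_e = stats::median(.data$abs_e),
      est_q25 = stats::quantile(.data$estimate_kcal, 0.25, names = FALSE),
      est_q50 = stats::quantile(.data$estimate_kcal, 0.50, names = FALSE),
      est_q75 = stats::quantile(.data$estimate_kcal, 0.75, names = FALSE),
      .groups = "drop"
    )
  tibble::as_tibble(quiz)[, c("food_id", "energy_kcal")] %>%
    dplyr::left_join(stats_tbl, by = "food_id") %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}
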