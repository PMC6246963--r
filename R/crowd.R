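# participants x foods estimate matrix (NA where unanswered), quiz column order
response_matrix <- function(responses, quiz) {
  wide <- responses %>%
    tidyr::pivot_wider(id_cols = "participant_id",
                       names_from = "food_id",
                       values_from = "estimate_kcal")
  m <- as.matrix(wide[, intersect(quiz$food_id, names(wide)), drop = FALSE])
  rownames(m) <- wide$participant_id
  m
}

aggregate_crowd <- function(m, rows, aggregator) {
  sub <- m[rows, , drop = FALSE]
  if (aggregator == "mean") {
    colMeans(sub, na.rm = TRUE)
  } else {
    apply(sub, 2, stats::median, na.rm = TRUE)
  }
}

#' Consensus estimate of a random crowd of k participants
#'
#' Samples `k` participants without replacement (one shared draw across all
#' foods: a crowd is a set of people), aggregates their estimates per food
#' with the mean (the default, "the average of k randomly selected
#' participants") or the median, and scores the consensus against ground
#' truth with the same rules as individual responses: the crowd's discrete
#' accuracy `D` is the number of foods whose consensus lies within 20% of
#' truth.
#'
#' @param responses Response tibble.
#' @param quiz A `quiz_spec`.
#' @param k Crowd size; must not exceed the number of responding
#'   participants.
#' @param aggregator `"mean"` or `"median"`.
#' @param seed Integer seed for the participant draw.
#' @return An object of class `crowd_result`; `tidy()` gives the per-food
#'   consensus table, `glance()` the one-row summary (`crowd_D`,
#'   `crowd_mean_abs_e_kcal`, `crowd_mean_abs_eta`).
#' @export
crowd_estimate <- function(responses, quiz, k,
                           aggregator = c("mean", "median"), seed = 1L) {
  aggregator <- match.arg(aggregator)
  m <- response_matrix(responses, quiz)
  if (k > nrow(m)) {
    abort(sprintf("crowd size k = %d exceeds the %d available participants",
                  k, nrow(m)))
  }
  set.seed(seed)
  rows <- sample.int(nrow(m), k)
  agg <- aggregate_crowd(m, rows, aggregator)

  consensus <- tibble::tibble(
    participant_id = "crowd",
    food_id = names(agg),
    estimate_kcal = unname(agg)
  ) %>% dplyr::filter(!is.na(.data$estimate_kcal))
  metrics <- compute_metrics(consensus, quiz)

  structure(
    list(
      k = k, aggregator = aggregator, seed = seed,
      members = rownames(m)[rows],
      per_food = metrics %>% dplyr::select(-"participant_id"),
      crowd_D = sum(metrics$correct20),
      crowd_mean_abs_e_kcal = mean(metrics$abs_e),
      crowd_mean_abs_eta = mean(abs(metrics$eta))
    ),
    class = "crowd_result"
  )
}

#' @exportS3Method base::print
print.crowd_result <- function(x, ...) {
  cat(sprintf(
    "Crowd of %d (%s): D = %d/%d, mean |e| = %.1f kcal (%.1f%%)\n",
    x$k, x$aggregator, x$crowd_D, nrow(x$per_food),
    x$crowd_mean_abs_e_kcal, 100 * x$crowd_mean_abs_eta
  ))
  invisible(x)
}

#' @rdname crowd_estimate
#' @param x A `crowd_result`.
#' @param ... Unused.
#' @export
tidy.crowd_result <- function(x, ...) x$per_food

#' @rdname crowd_estimate
#' @export
glance.crowd_result <- function(x, ...) {
  tibble::tibble(
    k = x$k, aggregator = x$aggregator, crowd_D = x$crowd_D,
    crowd_mean_abs_e_kcal = x$crowd_mean_abs_e_kcal,
    crowd_mean_abs_eta = x$crowd_mean_abs_eta
  )
}

#' Consensus convergence as the crowd grows
#'
#' For each food and each crowd size in `k_grid`, draws `n_draws` random
#' crowds and records the mean and SD (across draws) of the aggregated
#' estimate. On unbiased data the SD shrinks roughly as \eqn{1/\sqrt k}
#' (slightly faster for k near the cohort size, because crowds are drawn
#' without replacement), which is the rapid-consensus behaviour seen when
#' responses are plotted against a log-scaled crowd size.
#'
#' @inheritParams crowd_estimate
#' @param k_grid Increasing vector of crowd sizes.
#' @param n_draws Random crowds per size.
#' @return A tibble of class `crowd_convergence`: `food_id`, `truth_kcal`,
#'   `k`, `mean_estimate`, `sd_estimate`.
#' @export
convergence_curve <- function(responses, quiz, k_grid = c(1, 2, 5, 10, 20,
                                                          50, 100, 200),
                              n_draws = 100,
                              aggregator = c("mean", "median"), seed = 1L) {
  aggregator <- match.arg(aggregator)
  if (is.unsorted(k_grid, strictly = TRUE)) {
    abort("k_grid must be strictly increasing")
  }
  m <- response_matrix(responses, quiz)
  k_grid <- k_grid[k_grid <= nrow(m)]
  set.seed(seed)
  out <- purrr::map_dfr(k_grid, function(k) {
    draws <- vapply(seq_len(n_draws), function(b) {
      aggregate_crowd(m, sample.int(nrow(m), k), aggregator)
    }, numeric(ncol(m)))
    tibble::tibble(
      food_id = colnames(m),
      k = k,
      mean_estimate = unname(rowMeans(draws)),
      sd_estimate = unname(apply(draws, 1, stats::sd))
    )
  })
  out <- out %>%
    dplyr::left_join(
      tibble::tibble(food_id = quiz$food_id, truth_kcal = quiz$energy_kcal),
      by = "food_id"
    ) %>%
    dplyr::relocate("truth_kcal", .after = "food_id")
  class(out) <- c("crowd_convergence", class(out))
  out
}

crowd_measure <- function(agg, truth, measure) {
  if (measure == "abs_e") mean(abs(agg - truth), na.rm = TRUE)
  else mean(abs(agg - truth) / truth, na.rm = TRUE)
}

#' Bootstrap comparison of two crowd sizes
#'
#' Tests whether a crowd of `k1` is any more or less accurate than a crowd
#' of `k2` (the original finding: 10 heads are statistically as good as
#' 1000). Each of `B` iterations draws independent crowds of size `k1` and
#' `k2`, aggregates each with the mean, scores each by its mean absolute
#' error across foods (kcal by default, percent via `measure = "abs_eta"`),
#' and records the difference. The two-sided p-value asks whether the
#' difference crosses zero more or less often than chance: an exact sign
#' test on the `B` differences (`2 * min` binomial tail, capped at 1; ties
#' at exactly zero are dropped, and a fully degenerate cohort gives p = 1).
#' With `k1 = k2` the difference is symmetric about zero by construction,
#' so the test is type-I calibrated.
#'
#' @inheritParams crowd_estimate
#' @param k1,k2 Crowd sizes to compare.
#' @param B Bootstrap iterations (>= 100).
#' @param measure `"abs_e"` (kcal) or `"abs_eta"` (fraction of truth).
#' @return An object of class `crowd_boot`; `glance()` gives a one-row
#'   tibble with the observed mean difference and `p_value`.
#' @export
bootstrap_crowd_test <- function(responses, quiz, k1, k2, B = 1000,
                                 seed = 1L, measure = c("abs_e", "abs_eta")) {
  measure <- match.arg(measure)
  if (B < 100) abort("B must be at least 100")
  m <- response_matrix(responses, quiz)
  n <- nrow(m)
  if (max(k1, k2) > n) {
    abort(sprintf("crowd sizes (%d, %d) exceed the %d available participants",
                  k1, k2, n))
  }
  truth <- quiz$energy_kcal[match(colnames(m), quiz$food_id)]
  set.seed(seed)
  diffs <- vapply(seq_len(B), function(b) {
    a1 <- colMeans(m[sample.int(n, k1), , drop = FALSE], na.rm = TRUE)
    a2 <- colMeans(m[sample.int(n, k2), , drop = FALSE], na.rm = TRUE)
    crowd_measure(a1, truth, measure) - crowd_measure(a2, truth, measure)
  }, numeric(1))

  # exact two-sided sign test on the bootstrap differences: does the
  # difference cross zero more or less often than chance? (With k1 = k2 the
  # difference is exactly symmetric about 0, so this is calibrated.)
  wins <- sum(diffs > 0)
  losses <- sum(diffs < 0)
  m_eff <- wins + losses
  p <- if (m_eff == 0) 1 else {
    min(1, 2 * stats::pbinom(min(wins, losses), m_eff, 0.5))
  }

  structure(
    list(k1 = k1, k2 = k2, B = B, measure = measure, seed = seed,
         statistic_observed = mean(diffs), diffs = diffs, p_value = p),
    class = "crowd_boot"
  )
}

#' @exportS3Method base::print
print.crowd_boot <- function(x, ...) {
  cat(sprintf(
    "Bootstrap crowd test: k = %d vs %d, B = %d, mean diff (%s) = %.3f, P = %.3f\n",
    x$k1, x$k2, x$B, x$measure, x$statistic_observed, x$p_value
  ))
  invisible(x)
}

#' @rdname bootstrap_crowd_test
#' @param x A `crowd_boot` object.
#' @param ... Unused.
#' @export
glance.crowd_boot <- function(x, ...) {
  tibble::tibble(
    k1 = x$k1, k2 = x$k2, B = x$B, measure = x$measure,
    statistic_observed = x$statistic_observed, p_value = x$p_value
  )
}

#' @rdname bootstrap_crowd_test
#' @export
tidy.crowd_boot <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$B), diff = x$diffs)
}

#' How many random nonexperts does it take to beat the best expert?
#'
#' Scores each expert individually (mean |e| over the foods they answered),
#' then, for crowd sizes 1..`k_max`, averages over `n_draws` random
#' nonexpert crowds the crowd-consensus mean |e|. The minimal crowd size
#' whose average performance is strictly better than the best (lowest-error)
#' expert is reported; if no size up to `k_max` beats the best expert the
#' result is flagged `beaten = FALSE`.
#'
#' @inheritParams crowd_estimate
#' @param participants Participant tibble with `is_expert`.
#' @param k_max Largest crowd size to try.
#' @param n_draws Random crowds per size.
#' @param measure `"abs_e"` (kcal) or `"abs_eta"`.
#' @return An object of class `expert_comparison` with the per-k curve
#'   (`tidy()`) and the one-row summary (`glance()`: `best_expert_mean`,
#'   `expert_mean`, `min_k`, `beaten`).
#' @export
expert_comparison <- function(responses, participants, quiz, k_max = 10,
                              n_draws = 200, seed = 1L,
                              measure = c("abs_e", "abs_eta")) {
  measure <- match.arg(measure)
  experts <- participants$participant_id[participants$is_expert]
  if (length(experts) == 0) abort("no experts in the participant table")

  metrics <- compute_metrics(responses, quiz)
  col <- if (measure == "abs_e") "mean_abs_e_kcal" else "mean_abs_eta"
  expert_scores <- participant_summary(
    metrics %>% dplyr::filter(.data$participant_id %in% experts)
  )
  best_expert <- min(expert_scores[[col]])
  expert_mean <- mean(expert_scores[[col]])

  nonexp <- responses %>%
    dplyr::filter(!.data$participant_id %in% experts)
  m <- response_matrix(nonexp, quiz)
  truth <- quiz$energy_kcal[match(colnames(m), quiz$food_id)]
  k_max <- min(k_max, nrow(m))
  set.seed(seed)
  curve <- purrr::map_dfr(seq_len(k_max), function(k) {
    vals <- vapply(seq_len(n_draws), function(b) {
      crowd_measure(colMeans(m[sample.int(nrow(m), k), , drop = FALSE],
                             na.rm = TRUE), truth, measure)
    }, numeric(1))
    tibble::tibble(k = k, crowd_mean = mean(vals), crowd_sd = stats::sd(vals))
  })
  beats <- which(curve$crowd_mean < best_expert)
  structure(
    list(
      measure = measure, curve = curve,
      best_expert_mean = best_expert, expert_mean = expert_mean,
      min_k = if (length(beats) > 0) curve$k[beats[1]] else NA_integer_,
      beaten = length(beats) > 0
    ),
    class = "expert_comparison"
  )
}

#' @exportS3Method base::print
print.expert_comparison <- function(x, ...) {
  if (x$beaten) {
    cat(sprintf(
      "A crowd of %d nonexperts outperforms the best expert (%.1f vs %.1f %s)\n",
      x$min_k, x$curve$crowd_mean[x$curve$k == x$min_k],
      x$best_expert_mean, x$measure
    ))
  } else {
    cat(sprintf("No crowd up to k = %d beats the best expert (%.1f %s)\n",
                max(x$curve$k), x$best_expert_mean, x$measure))
  }
  invisible(x)
}

#' @rdname expert_comparison
#' @param x An `expert_comparison` object.
#' @param ... Unused.
#' @export
tidy.expert_comparison <- function(x, ...) x$curve

#' @rdname expert_comparison
#' @export
glance.expert_comparison <- function(x, ...) {
  tibble::tibble(
    measure = x$measure, best_expert_mean = x$best_expert_mean,
    expert_mean = x$expert_mean, min_k = x$min_k, beaten = x$beaten
  )
}
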