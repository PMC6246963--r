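test_that("the exhaustive crowd reproduces per-food grand means exactly", {
  cohort <- clean_cohort(40, seed = 6)
  n <- dplyr::n_distinct(cohort$responses$participant_id)
  cr <- crowd_estimate(cohort$responses, table1, k = n, seed = 1)
  grand <- cohort$responses %>%
    dplyr::group_by(food_id) %>%
    dplyr::summarise(m = mean(estimate_kcal))
  per_food <- tidy(cr)
  expect_equal(
    per_food$estimate_kcal[match(grand$food_id, per_food$food_id)],
    grand$m
  )
  # single code path: crowd D equals the metric rules applied to consensus
  expect_equal(cr$crowd_D, sum(compute_metrics(
    tibble::tibble(participant_id = "crowd", food_id = per_food$food_id,
                   estimate_kcal = per_food$estimate_kcal),
    table1
  )$correct20))
})

test_that("a singleton crowd is just one participant", {
  cohort <- clean_cohort(15, seed = 7)
  cr <- crowd_estimate(cohort$responses, table1, k = 1, seed = 42)
  member <- cr$members
  own <- cohort$responses %>% dplyr::filter(participant_id == member)
  per_food <- tidy(cr)
  expect_equal(
    per_food$estimate_kcal[match(own$food_id, per_food$food_id)],
    own$estimate_kcal
  )
  expect_error(crowd_estimate(cohort$responses, table1, k = 16),
               "exceeds")
})

test_that("convergence curve is flat at truth for a deterministic cohort", {
  cohort <- clean_cohort(30, seed = 1, sigma_noise = 0, sd_participant = 0,
                         sd_food = 0)
  curve <- convergence_curve(cohort$responses, table1, k_grid = c(1, 5, 10),
                             n_draws = 20, seed = 2)
  expect_equal(curve$mean_estimate, curve$truth_kcal)
  expect_equal(curve$sd_estimate, rep(0, nrow(curve)))
})

test_that("k_grid = 1 reproduces the distribution of single answers", {
  cohort <- clean_cohort(50, seed = 3)
  curve <- convergence_curve(cohort$responses, table1, k_grid = 1,
                             n_draws = 500, seed = 9)
  singles <- cohort$responses %>%
    dplyr::group_by(food_id) %>%
    dplyr::summarise(m = mean(estimate_kcal), s = stats::sd(estimate_kcal))
  j <- match(curve$food_id, singles$food_id)
  # draws of one participant: mean across draws approaches the mean of singles
  expect_true(all(abs(curve$mean_estimate - singles$m[j]) <
                    4 * singles$s[j] / sqrt(500)))
  expect_error(
    convergence_curve(cohort$responses, table1, k_grid = c(10, 5)),
    "increasing"
  )
})

test_that("bootstrap test is deterministic and handles degenerate data", {
  cohort <- clean_cohort(60, seed = 12)
  b1 <- bootstrap_crowd_test(cohort$responses, table1, 5, 30, B = 200,
                             seed = 4)
  b2 <- bootstrap_crowd_test(cohort$responses, table1, 5, 30, B = 200,
                             seed = 4)
  expect_identical(b1$p_value, b2$p_value)
  expect_true(b1$p_value > 0 && b1$p_value <= 1)

  # all responses identical -> every difference 0 -> p = 1
  flat <- toy_responses(rep(0, 12))
  bf <- bootstrap_crowd_test(flat, table1, 3, 6, B = 100, seed = 1)
  expect_equal(bf$p_value, 1)
})

test_that("bootstrap p-values are invariant to participant relabeling", {
  cohort <- clean_cohort(40, seed = 13)
  b1 <- bootstrap_crowd_test(cohort$responses, table1, 5, 20, B = 200,
                             seed = 7)
  relabeled <- cohort$responses %>%
    dplyr::mutate(participant_id = paste0("XX_", participant_id))
  b2 <- bootstrap_crowd_test(relabeled, table1, 5, 20, B = 200, seed = 7)
  expect_identical(b1$p_value, b2$p_value)
})

test_that("the bootstrap detects a genuinely worse small crowd", {
  cohort <- clean_cohort(300, seed = 14, sigma_noise = 0.5)
  b <- bootstrap_crowd_test(cohort$responses, table1, k1 = 2, k2 = 150,
                            B = 500, seed = 5)
  expect_gt(b$statistic_observed, 0)  # small crowds have larger |e|
  expect_lt(b$p_value, 0.05)
})

test_that("expert comparison finds the minimal crowd or flags unbeatable", {
  cohort <- simulate_cohort(
    table1,
    sim_config(n_participants = 100, n_experts = 4, seed = 15,
               p_invalid_bmi = 0, p_missing_gender = 0)
  )
  ec <- expert_comparison(cohort$responses, cohort$participants, table1,
                          k_max = 8, n_draws = 100, seed = 2)
  g <- glance(ec)
  if (g$beaten) {
    curve <- tidy(ec)
    expect_lt(curve$crowd_mean[curve$k == g$min_k], g$best_expert_mean)
    if (g$min_k > 1) {
      expect_true(all(curve$crowd_mean[curve$k < g$min_k] >=
                        g$best_expert_mean))
    }
  } else {
    expect_true(is.na(g$min_k))
  }

  # a perfect expert cannot be beaten
  perfect <- toy_responses(rep(0, 1))
  perfect$participant_id <- "E01"
  crowd_r <- clean_cohort(20, seed = 16)$responses
  parts <- dplyr::bind_rows(
    toy_participants("E01", is_expert = TRUE),
    toy_participants(unique(crowd_r$participant_id))
  )
  ec2 <- expert_comparison(dplyr::bind_rows(perfect, crowd_r), parts,
                           table1, k_max = 5, n_draws = 50, seed = 3)
  expect_false(ec2$beaten)
  expect_true(is.na(ec2$min_k))

  expect_error(
    expert_comparison(crowd_r, toy_participants(unique(crowd_r$participant_id)),
                      table1),
    "no experts"
  )
})

test_that("expert copies of the crowd: full crowd wins iff consensus beats best individual", {
  # brute-force check on a tiny instance where experts = nonexperts
  resp_non <- toy_responses(c(14, -60, 90))
  resp_exp <- resp_non %>%
    dplyr::mutate(participant_id = paste0("E_", participant_id))
  parts <- dplyr::bind_rows(
    toy_participants(unique(resp_non$participant_id)),
    toy_participants(unique(resp_exp$participant_id), is_expert = TRUE)
  )
  all_resp <- dplyr::bind_rows(resp_non, resp_exp)
  ec <- expert_comparison(all_resp, parts, table1, k_max = 3,
                          n_draws = 50, seed = 1)
  best_individual <- min(participant_summary(
    compute_metrics(resp_non, table1)
  )$mean_abs_e_kcal)
  consensus <- crowd_estimate(resp_non, table1, k = 3, seed = 1)
  curve <- tidy(ec)
  expect_equal(
    curve$crowd_mean[curve$k == 3] < best_individual,
    consensus$crowd_mean_abs_e_kcal < best_individual
  )
  expect_equal(curve$crowd_mean[curve$k == 3],
               consensus$crowd_mean_abs_e_kcal)
})
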