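test_that("density-mass correlation matches the published table value", {
  expect_equal(round(density_mass_correlation(table1), 2), -0.70)
})

test_that("density-mass correlation edge cases", {
  # two foods -> correlation is exactly +/- 1
  two <- tibble::as_tibble(table1)[1:2, ]
  expect_equal(abs(density_mass_correlation(two)), 1)
  # constant density -> undefined, reported missing
  const <- tibble::as_tibble(table1)[1:3, ]
  const$energy_kcal <- const$mass_g * 2
  expect_true(is.na(density_mass_correlation(const)))
  expect_error(density_mass_correlation(tibble::as_tibble(table1)[1, ]),
               "at least 2")
})

test_that("all four registered models fit and return tidy results", {
  cohort <- clean_cohort(80, seed = 31, beta_density = 0.2,
                         beta_male = 0.15)
  metrics <- compute_metrics(cohort$responses, table1)
  for (mn in bias_models()) {
    f <- fit_bias_model(metrics, cohort$participants, table1, mn)
    expect_s3_class(f, "bias_fit")
    expect_true(f$converged)
    g <- glance(f)
    expect_equal(g$model_name, mn)
    expect_true(g$r_squared >= 0 && g$r_squared <= 1)
    td <- tidy(f)
    expect_true(all(c("term", "estimate", "std.error", "p.value") %in%
                      names(td)))
    expect_true(all(td$p.value >= 0 & td$p.value <= 1))
  }
  expect_error(
    fit_bias_model(metrics[metrics$participant_id == "P00001", ],
                   cohort$participants, table1, "density_bias"),
    "at least 2"
  )
})

test_that("r_squared is 1 when the outcome is the model's own prediction", {
  cohort <- clean_cohort(40, seed = 32, beta_density = 0.3)
  metrics <- compute_metrics(cohort$responses, table1)
  f <- fit_bias_model(metrics, cohort$participants, table1, "density_bias")
  metrics2 <- metrics
  # frame rows align with metrics rows; a tiny jitter keeps the residual
  # variance identifiable (an exactly zero-residual mixed model is ill-posed)
  set.seed(1)
  metrics2$e <- stats::fitted(f$fit) +
    stats::rnorm(nrow(metrics2), 0, 1e-4)
  f2 <- fit_bias_model(metrics2, cohort$participants, table1, "density_bias")
  expect_equal(f2$r_squared, 1, tolerance = 1e-6)

  # the exactly-degenerate case fails loudly, never silently
  metrics3 <- metrics
  metrics3$e <- stats::fitted(f$fit)
  f3 <- fit_bias_model(metrics3, cohort$participants, table1, "density_bias")
  expect_false(f3$converged)
  expect_true(nchar(paste(f3$notes, collapse = "")) > 0)
})

test_that("r_squared is invariant to rescaling the outcome's units", {
  cohort <- clean_cohort(50, seed = 33, beta_density = 0.25)
  metrics <- compute_metrics(cohort$responses, table1)
  f1 <- fit_bias_model(metrics, cohort$participants, table1, "density_bias")

  quiz3 <- scale_quiz(table1, 3)
  resp3 <- cohort$responses %>%
    dplyr::mutate(estimate_kcal = estimate_kcal * 3)
  metrics3 <- compute_metrics(resp3, quiz3)
  f3 <- fit_bias_model(metrics3, cohort$participants, quiz3, "density_bias")
  # e is 3x larger but the proportion of variance described is unchanged
  expect_equal(f3$r_squared, f1$r_squared, tolerance = 1e-6)
  expect_equal(tidy(f3)$estimate[2], 3 * tidy(f1)$estimate[2],
               tolerance = 1e-4)
})

test_that("with zero random-effect variance the LMM agrees with plain OLS", {
  cohort <- clean_cohort(60, seed = 34, beta_density = 0.3,
                         sd_participant = 0, sd_food = 0)
  metrics <- compute_metrics(cohort$responses, table1)
  f <- fit_bias_model(metrics, cohort$participants, table1, "density_bias")

  qt <- tibble::tibble(
    food_id = table1$food_id,
    density_c = log(energy_density(table1)) - mean(log(energy_density(table1)))
  )
  frame <- dplyr::inner_join(metrics, qt, by = "food_id")
  ols <- stats::lm(e ~ density_c, data = frame)
  lmm_beta <- tidy(f)$estimate
  ols_beta <- unname(stats::coef(ols))
  expect_lt(abs(lmm_beta[2] - ols_beta[2]) / abs(ols_beta[2]), 0.01)
})

test_that("density transform is switchable between log and raw", {
  cohort <- clean_cohort(40, seed = 35, beta_density = 0.3)
  metrics <- compute_metrics(cohort$responses, table1)
  f_log <- fit_bias_model(metrics, cohort$participants, table1,
                          "density_bias", density_transform = "log")
  f_raw <- fit_bias_model(metrics, cohort$participants, table1,
                          "density_bias", density_transform = "raw")
  expect_false(isTRUE(all.equal(tidy(f_log)$estimate[2],
                                tidy(f_raw)$estimate[2])))
  expect_gt(tidy(f_raw)$estimate[2], 0)  # sign is preserved either way
})

test_that("density-bias curve orders foods by density and tracks the trend", {
  cohort <- clean_cohort(200, seed = 36, beta_density = 0.5,
                         sigma_noise = 0.3)
  metrics <- compute_metrics(cohort$responses, table1)
  curve <- density_bias_curve(metrics, table1)
  expect_equal(nrow(curve), 20)
  expect_false(is.unsorted(curve$energy_density))
  rho <- stats::cor(curve$energy_density, curve$mean_e, method = "spearman")
  expect_gt(rho, 0.5)

  single <- density_bias_curve(
    metrics[metrics$food_id == "potato", ],
    tibble::as_tibble(table1)[table1$food_id == "potato", ]
  )
  expect_equal(nrow(single), 1)
})
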