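#' Configuration for the synthetic respondent cohort
#'
#' The generator produces calorie estimates on the log scale: for participant
#' `i` and food `j`,
#' \deqn{\log \hat c_{ij} = \log c_j + \beta_d z_j + \beta_m 1[male_i] +
#'   \beta_a a_i + \beta_{bd} (bmi_i - 25) z_j + u_i + v_j + \epsilon_{ij}}
#' where `z_j` is the centered log energy density of food `j`, `a_i` the
#' 0-based age-bin index, `u_i ~ N(0, sd_participant^2)` and
#' `v_j ~ N(0, sd_food^2)` random intercepts, and
#' `eps_ij ~ N(0, sigma_noise^2)` multiplicative estimation noise. Estimates
#' falling outside the allowed answer range are redrawn (noise term only) up
#' to `max_resample` times, then clipped — mirroring a quiz interface that
#' forces answers into the range.
#'
#' All bias coefficients default to 0 (the original study printed no
#' log-scale effect sizes); the noise scales default to values giving an
#' error magnitude comparable to the reported crowd (mean absolute percent
#' error around 50-60%). `p_female = 0.62` and `bmi_mean = 27.5` echo the
#' reported cohort skew. `p_invalid_bmi` and `p_missing_gender` deliberately
#' inject records that the quality filters must remove.
#'
#' @param n_participants,n_experts Cohort sizes; experts are generated from
#'   the same distribution (the study found no expert advantage) but flagged.
#' @param seed Master integer seed; per-stage substreams are derived from it.
#' @param sigma_noise SD of the log-scale estimation noise.
#' @param beta_density Bias per unit centered log energy density.
#' @param beta_male Additive male effect on the log estimate.
#' @param beta_age Effect per age-bin step.
#' @param beta_bmi_density BMI-by-density interaction (per kg/m^2 above 25).
#' @param sd_participant,sd_food SDs of the random intercepts.
#' @param p_female Probability a participant is female.
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2).
#' @param p_invalid_bmi Probability of an implausible BMI (< 15 or > 50).
#' @param p_missing_gender Probability gender is not reported.
#' @param age_probs Sampling weights over [age_bins()] (defaults skew young,
#'   as in the social-media cohort).
#' @param round_kcal Round estimates to whole kcal (participants typed
#'   integers)? Default TRUE.
#' @param max_resample Redraw budget before clipping at the range bounds.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 2028,
                       n_experts = 5,
                       seed = 1L,
                       sigma_noise = 0.45,
                       beta_density = 0,
                       beta_male = 0,
                       beta_age = 0,
                       beta_bmi_density = 0,
                       sd_participant = 0.25,
                       sd_food = 0.15,
                       p_female = 0.62,
                       bmi_mean = 27.5,
                       bmi_sd = 6,
                       p_invalid_bmi = 0.025,
                       p_missing_gender = 0.02,
                       age_probs = c(0.08, 0.42, 0.30, 0.12, 0.05, 0.02, 0.01),
                       round_kcal = TRUE,
                       max_resample = 100L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_experts = as.integer(n_experts),
    seed = as.integer(seed),
    sigma_noise = sigma_noise, beta_density = beta_density,
    beta_male = beta_male, beta_age = beta_age,
    beta_bmi_density = beta_bmi_density,
    sd_participant = sd_participant, sd_food = sd_food,
    p_female = p_female, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    p_invalid_bmi = p_invalid_bmi, p_missing_gender = p_missing_gender,
    age_probs = age_probs, round_kcal = isTRUE(round_kcal),
    max_resample = as.integer(max_resample)
  )
  probs <- c(p_female, p_invalid_bmi, p_missing_gender)
  if (any(probs < 0 | probs > 1)) abort("sim_config: probabilities must be in [0, 1]")
  sds <- c(sigma_noise, sd_participant, sd_food, bmi_sd)
  if (any(sds < 0)) abort("sim_config: SDs must be non-negative")
  if (cfg$n_participants < 0 || cfg$n_experts < 0) {
    abort("sim_config: cohort sizes must be non-negative")
  }
  if (length(age_probs) != length(age_levels())) {
    abort("sim_config: age_probs must have one weight per age bin")
  }
  if (cfg$max_resample < 1) abort("sim_config: max_resample must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a respondent cohort and its quiz responses
#'
#' Draws demographics, random intercepts and log-scale noise per
#' [sim_config()] and produces one estimate per participant and food,
#' truncated to the quiz answer range. Deterministic given the config seed.
#'
#' @param quiz A `quiz_spec` tibble.
#' @param config A [sim_config()] object.
#' @return A list with tibbles `participants` and `responses` (same shapes as
#'   [read_responses()] output).
#' @export
#' @examples
#' quiz <- load_quiz("table1")
#' cohort <- simulate_cohort(quiz, sim_config(n_participants = 50, seed = 7))
#' nrow(cohort$responses)  # 55 participants (50 + 5 experts) x 20 foods
simulate_cohort <- function(quiz, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_participants + config$n_experts
  if (n_total == 0) {
    return(list(
      participants = tibble::tibble(
        participant_id = character(), gender = character(),
        age_group = character(), bmi_kg_m2 = double(), is_expert = logical()
      ),
      responses = tibble::tibble(
        participant_id = character(), food_id = character(),
        estimate_kcal = double()
      )
    ))
  }

  participants <- local({
    set.seed(sub_seed(config$seed, 1L))
    id <- c(
      if (config$n_participants > 0)
        sprintf("P%05d", seq_len(config$n_participants)),
      if (config$n_experts > 0) sprintf("E%03d", seq_len(config$n_experts))
    )
    gender <- sample(c("female", "male"), n_total, replace = TRUE,
                     prob = c(config$p_female, 1 - config$p_female))
    gender[stats::runif(n_total) < config$p_missing_gender] <- "missing"
    bmi <- stats::rnorm(n_total, config$bmi_mean, config$bmi_sd)
    invalid <- stats::runif(n_total) < config$p_invalid_bmi
    n_inv <- sum(invalid)
    if (n_inv > 0) {
      low <- stats::runif(n_inv) < 0.5
      bmi[invalid] <- ifelse(low,
                             stats::runif(n_inv, 8, 14.9),
                             stats::runif(n_inv, 50.1, 75))
    }
    age_group <- sample(age_levels(), n_total, replace = TRUE,
                        prob = config$age_probs)
    tibble::tibble(
      participant_id = id, gender = gender, age_group = age_group,
      bmi_kg_m2 = bmi,
      is_expert = rep(c(FALSE, TRUE),
                      c(config$n_participants, config$n_experts))
    )
  })

  J <- nrow(quiz)
  logd <- log(energy_density(quiz))
  z <- logd - mean(logd)
  floor_k <- quiz_floor(quiz)
  ceil_k <- quiz_ceiling(quiz)

  set.seed(sub_seed(config$seed, 2L))
  u <- stats::rnorm(n_total, 0, config$sd_participant)
  v <- stats::rnorm(J, 0, config$sd_food)

  # participant-major long layout: participant i occupies rows (i-1)*J + 1:J
  i_idx <- rep(seq_len(n_total), each = J)
  j_idx <- rep(seq_len(J), times = n_total)
  male <- as.numeric(participants$gender == "male")[i_idx]
  agebin <- age_bin_index(participants$age_group)[i_idx]
  bmi_c <- (participants$bmi_kg_m2 - 25)[i_idx]
  zz <- z[j_idx]

  mu <- log(quiz$energy_kcal)[j_idx] +
    config$beta_density * zz +
    config$beta_male * male +
    config$beta_age * agebin +
    config$beta_bmi_density * bmi_c * zz +
    u[i_idx] + v[j_idx]

  set.seed(sub_seed(config$seed, 3L))
  est <- exp(mu + stats::rnorm(length(mu), 0, config$sigma_noise))
  for (iter in seq_len(config$max_resample)) {
    out <- which(est < floor_k | est > ceil_k)
    if (length(out) == 0) break
    est[out] <- exp(mu[out] + stats::rnorm(length(out), 0, config$sigma_noise))
  }
  est <- pmin(pmax(est, floor_k), ceil_k)
  if (config$round_kcal) est <- round(est)

  responses <- tibble::tibble(
    participant_id = participants$participant_id[i_idx],
    food_id = quiz$food_id[j_idx],
    estimate_kcal = est
  )
  list(participants = participants, responses = responses)
}

#' Append near-duplicate foods sharing a source food's errors
#'
#' Test fixture for the error-correlation network: each copy re-uses the
#' source food's per-participant proportional errors plus small independent
#' log-normal noise, so copy and source are strongly correlated columns.
#'
#' @param responses Response tibble.
#' @param quiz The matching `quiz_spec`.
#' @param food_id Source food to duplicate.
#' @param copies Number of near-duplicates (0 returns the inputs unchanged).
#' @param noise_sd SD of the independent log-scale noise added to each copy.
#' @param seed Integer seed for the added noise.
#' @return A list with the augmented `responses` and `quiz` (copies named
#'   `<food_id>_dup1`, ...).
#' @export
perturb_duplicate_foods <- function(responses, quiz, food_id, copies,
                                    noise_sd = 0.05, seed = 1L) {
  if (!food_id %in% quiz$food_id) {
    abort(sprintf("unknown food_id: %s", food_id))
  }
  if (copies == 0) return(list(responses = responses, quiz = quiz))

  src <- responses %>% dplyr::filter(.data$food_id == !!food_id)
  src_row <- quiz[quiz$food_id == food_id, ]
  set.seed(sub_seed(seed, 9L))
  new_resp <- purrr::map_dfr(seq_len(copies), function(k) {
    src %>% dplyr::mutate(
      food_id = paste0(!!food_id, "_dup", k),
      estimate_kcal = .data$estimate_kcal *
        exp(stats::rnorm(dplyr::n(), 0, noise_sd))
    )
  })
  new_quiz_rows <- purrr::map_dfr(seq_len(copies), function(k) {
    src_row %>% dplyr::mutate(
      food_id = paste0(!!food_id, "_dup", k),
      name = paste(src_row$name, "copy", k)
    )
  })
  quiz2 <- new_quiz_spec(dplyr::bind_rows(tibble::as_tibble(quiz), new_quiz_rows),
                         quiz_floor(quiz), quiz_ceiling(quiz))
  list(responses = dplyr::bind_rows(responses, new_resp), quiz = quiz2)
}

#' Simulate planted block-structured proportional errors
#'
#' Generates a percent-error table with a planted partition: foods in the
#' same block share a per-participant latent factor (unit variance), plus
#' independent noise with SD `within_sd`, so the within-block error
#' correlation is `1 / (1 + within_sd^2)` and the between-block correlation
#' is 0. Used to validate cluster recovery in the error network.
#'
#' @param n_participants Number of simulated participants.
#' @param block_sizes Integer vector; one entry per block.
#' @param within_sd SD of the food-specific noise relative to the unit-SD
#'   block factor (default 0.5, within-block correlation 0.8).
#' @param seed Integer seed.
#' @return A tibble with `participant_id`, `food_id`, `eta`, and `block`
#'   (the planted label), directly usable by [error_correlation_matrix()].
#' @export
simulate_block_errors <- function(n_participants, block_sizes,
                                  within_sd = 0.5, seed = 1L) {
  set.seed(sub_seed(seed, 4L))
  n_blocks <- length(block_sizes)
  foods <- unlist(purrr::imap(block_sizes, function(sz, b) {
    sprintf("b%d_food%d", b, seq_len(sz))
  }))
  block_of <- rep(seq_len(n_blocks), times = block_sizes)
  g <- matrix(stats::rnorm(n_participants * n_blocks), n_participants)
  eta <- g[, block_of, drop = FALSE] +
    matrix(stats::rnorm(n_participants * length(foods), 0, within_sd),
           n_participants)
  tibble::tibble(
    participant_id = rep(sprintf("P%05d", seq_len(n_participants)),
                         times = length(foods)),
    food_id = rep(foods, each = n_participants),
    eta = as.vector(eta),
    block = rep(block_of, each = n_participants)
  )
}
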