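# Shared fixtures, built in code at test time.

table1 <- load_quiz("table1")

# cohort with no deliberate QC bait, for tests that want clean data
clean_config <- function(n, seed, ...) {
  sim_config(n_participants = n, n_experts = 0, seed = seed,
             p_invalid_bmi = 0, p_missing_gender = 0, ...)
}

clean_cohort <- function(n, seed, ...) {
  simulate_cohort(table1, clean_config(n, seed, ...))
}

# deterministic toy: every participant answers truth + offset kcal
toy_responses <- function(offsets, quiz = table1) {
  purrr::imap_dfr(offsets, function(off, i) {
    tibble::tibble(
      participant_id = sprintf("T%02d", i),
      food_id = quiz$food_id,
      estimate_kcal = pmin(pmax(quiz$energy_kcal + off, quiz_floor(quiz)),
                           quiz_ceiling(quiz))
    )
  })
}

# same quiz with all energies multiplied by f (via the CSV reader, so the
# result is a fully validated quiz_spec)
scale_quiz <- function(quiz, f) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    food_id = quiz$food_id, name = quiz$name, type = quiz$food_type,
    energy_kcal = quiz$energy_kcal * f, mass_g = quiz$mass_g,
    scaling = ifelse(quiz$has_reference_object, "yes", "no")
  ), path)
  load_quiz(path, estimate_floor_kcal = quiz_floor(quiz) * f,
            estimate_ceiling_kcal = quiz_ceiling(quiz) * f)
}

# same quiz with the reference-object flags randomly reassigned: the null
# world for the reference-object analysis (in the real layout the flag is
# confounded with portion energy)
scramble_refs <- function(quiz, seed) {
  set.seed(seed)
  flags <- sample(quiz$has_reference_object)
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    food_id = quiz$food_id, name = quiz$name, type = quiz$food_type,
    energy_kcal = quiz$energy_kcal, mass_g = quiz$mass_g,
    scaling = ifelse(flags, "yes", "no")
  ), path)
  load_quiz(path)
}

toy_participants <- function(ids, gender = "female", bmi = 25,
                             age_group = "25-34", is_expert = FALSE) {
  tibble::tibble(
    participant_id = ids,
    gender = rep_len(gender, length(ids)),
    age_group = rep_len(age_group, length(ids)),
    bmi_kg_m2 = rep_len(bmi, length(ids)),
    is_expert = rep_len(is_expert, length(ids))
  )
}
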