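#' Read response and participant tables
#'
#' Two CSV dialects are accepted. The two-file dialect has a response table
#' (`participant_id`, `food_id`, `estimate_kcal`) plus a demographics table
#' (`participant_id`, `gender`, `age_group`, and either `bmi_kg_m2` or
#' `height_cm`/`height_m` + `weight_kg`; optional logical `is_expert`). The
#' long single-file dialect repeats the demographic columns on every response
#' row. BMI is computed as weight(kg) / height(m)^2 when only height and
#' weight are given. An empty or absent gender is read as `"missing"` (and is
#' later removed by [filter_participants()]).
#'
#' @param path Responses CSV (either dialect).
#' @param participants_path Demographics CSV for the two-file dialect, or
#'   `NULL` for the long dialect.
#' @param quiz Optional `quiz_spec`; if supplied, unknown `food_id`s are
#'   reported as a warning (they are kept, so the caller can decide).
#' @return A list with tibbles `participants` (participant_id, gender,
#'   age_group, bmi_kg_m2, is_expert) and `responses` (participant_id,
#'   food_id, estimate_kcal).
#' @export
read_responses <- function(path, participants_path = NULL, quiz = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  assert_columns(raw, c("participant_id", "food_id", "estimate_kcal"),
                 "responses CSV")

  est <- suppressWarnings(as.numeric(raw$estimate_kcal))
  bad <- which(is.na(est) & !is.na(raw$estimate_kcal) & raw$estimate_kcal != "")
  if (length(bad) > 0) {
    abort(sprintf(
      "responses CSV: malformed estimate_kcal in row(s) %s (e.g. \"%s\")",
      paste(utils::head(bad, 10), collapse = ", "), raw$estimate_kcal[bad[1]]
    ))
  }
  responses <- tibble::tibble(
    participant_id = raw$participant_id,
    food_id = raw$food_id,
    estimate_kcal = est
  )

  demo_cols <- c("gender", "age_group", "bmi_kg_m2",
                 "height_cm", "height_m", "weight_kg", "is_expert")
  if (!is.null(participants_path)) {
    praw <- readr::read_csv(participants_path, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
    assert_columns(praw, "participant_id", "participants CSV")
    participants <- parse_participants(praw)
  } else if (any(demo_cols %in% names(raw))) {
    participants <- raw %>%
      dplyr::distinct(dplyr::across(dplyr::all_of(
        c("participant_id", intersect(demo_cols, names(raw)))
      ))) %>%
      parse_participants()
    if (anyDuplicated(participants$participant_id)) {
      dup <- unique(participants$participant_id[duplicated(participants$participant_id)])
      abort(sprintf(
        "long-format responses: inconsistent demographics for participant(s) %s",
        paste(utils::head(dup, 5), collapse = ", ")
      ))
    }
  } else {
    abort(paste0(
      "no demographics found: supply participants_path or use the long ",
      "dialect with demographic columns in the responses file"
    ))
  }

  orphans <- setdiff(responses$participant_id, participants$participant_id)
  if (length(orphans) > 0) {
    abort(sprintf("responses reference unknown participant_id(s): %s",
                  paste(utils::head(orphans, 5), collapse = ", ")))
  }
  if (!is.null(quiz)) {
    unknown <- setdiff(responses$food_id, quiz$food_id)
    if (length(unknown) > 0) {
      warn(sprintf("responses reference food_id(s) not in the quiz: %s",
                   paste(unknown, collapse = ", ")))
    }
  }
  list(participants = participants, responses = responses)
}

parse_participants <- function(praw) {
  n <- nrow(praw)
  num_col <- function(col, what) {
    if (!col %in% names(praw)) return(rep(NA_real_, n))
    x <- suppressWarnings(as.numeric(praw[[col]]))
    bad <- which(is.na(x) & !is.na(praw[[col]]) & praw[[col]] != "")
    if (length(bad) > 0) {
      abort(sprintf("participants: malformed %s in row(s) %s",
                    what, paste(utils::head(bad, 10), collapse = ", ")))
    }
    x
  }

  gender <- if ("gender" %in% names(praw)) tolower(praw$gender) else rep(NA_character_, n)
  gender[is.na(gender) | gender == ""] <- "missing"
  bad_g <- which(!gender %in% c("female", "male", "missing"))
  if (length(bad_g) > 0) {
    abort(sprintf("participants: unrecognised gender in row(s) %s",
                  paste(utils::head(bad_g, 10), collapse = ", ")))
  }

  age_group <- if ("age_group" %in% names(praw)) praw$age_group else rep(NA_character_, n)
  age_group[age_group == ""] <- NA_character_
  bad_a <- which(!is.na(age_group) & !age_group %in% age_levels())
  if (length(bad_a) > 0) {
    abort(sprintf(
      "participants: unknown age_group in row(s) %s (known bins: %s)",
      paste(utils::head(bad_a, 10), collapse = ", "),
      paste(age_levels(), collapse = ", ")
    ))
  }

  bmi <- num_col("bmi_kg_m2", "bmi_kg_m2")
  height_m <- num_col("height_m", "height_m")
  height_cm <- num_col("height_cm", "height_cm")
  weight <- num_col("weight_kg", "weight_kg")
  h <- ifelse(is.na(height_m), height_cm / 100, height_m)
  derived <- weight / h^2
  bmi <- ifelse(is.na(bmi), derived, bmi)

  is_expert <- if ("is_expert" %in% names(praw)) {
    tolower(praw$is_expert) %in% c("true", "yes", "1")
  } else {
    rep(FALSE, n)
  }

  tibble::tibble(
    participant_id = praw$participant_id,
    gender = gender,
    age_group = age_group,
    bmi_kg_m2 = bmi,
    is_expert = is_expert
  )
}

#' Write response and participant tables
#'
#' Writes the two-file CSV dialect read back by [read_responses()]. The
#' round trip is lossless: `gender = "missing"` and `NA` BMI are serialized
#' as empty fields and re-read as missing.
#'
#' @param participants,responses Tibbles as returned by [simulate_cohort()]
#'   or [read_responses()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_responses <- function(participants, responses, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_path <- file.path(dir, "participants.csv")
  r_path <- file.path(dir, "responses.csv")
  p_out <- participants %>%
    dplyr::mutate(gender = dplyr::if_else(.data$gender == "missing",
                                          NA_character_, .data$gender))
  readr::write_csv(p_out, p_path, na = "")
  readr::write_csv(responses, r_path, na = "")
  invisible(c(participants = p_path, responses = r_path))
}
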