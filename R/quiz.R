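#' Quiz specification: the foods with known ground truth
#'
#' A quiz specification is a tibble with one row per pictured food and the
#' ground-truth energy content, carrying the allowed answer range as
#' attributes. The packaged `"table1"` fixture holds the 20 foods of the
#' original online quiz (12 single-ingredient, 8 mixed dishes, energies from
#' 100 to 720 kcal), six of which were photographed next to a reference
#' object (credit card, fork) intended to convey scale.
#'
#' @param source Path to a quiz CSV, or `"table1"` for the packaged fixture.
#'   The CSV must have columns `food_id`, `name`, `type`, `energy_kcal`,
#'   `mass_g`, `scaling` (yes/no or TRUE/FALSE).
#' @param estimate_floor_kcal,estimate_ceiling_kcal Allowed answer range shown
#'   to participants; defaults 50 and 800 kcal.
#'
#' @return A tibble of class `quiz_spec` with columns `food_id`, `name`,
#'   `food_type`, `energy_kcal`, `mass_g`, `has_reference_object`,
#'   `single_ingredient`, and attributes `estimate_floor_kcal`,
#'   `estimate_ceiling_kcal`.
#' @export
#' @examples
#' quiz <- load_quiz("table1")
#' nrow(quiz)            # 20 foods
#' quiz_floor(quiz)      # 50 kcal
load_quiz <- function(source = "table1",
                      estimate_floor_kcal = 50,
                      estimate_ceiling_kcal = 800) {
  path <- if (identical(source, "table1")) {
    system.file("extdata", "table1_quiz.csv", package = "crowdcal",
                mustWork = TRUE)
  } else {
    source
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  assert_columns(raw, c("food_id", "name", "type", "energy_kcal", "mass_g",
                        "scaling"), "quiz CSV")

  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("quiz CSV: non-numeric %s in row(s) %s",
                    col, paste(bad, collapse = ", ")))
    }
    x
  }

  quiz <- tibble::tibble(
    food_id = raw$food_id,
    name = raw$name,
    food_type = tolower(raw$type),
    energy_kcal = num("energy_kcal"),
    mass_g = num("mass_g"),
    has_reference_object = tolower(raw$scaling) %in% c("yes", "true", "1"),
    single_ingredient = tolower(raw$type) != "mixed"
  )
  new_quiz_spec(quiz, estimate_floor_kcal, estimate_ceiling_kcal)
}

new_quiz_spec <- function(quiz, floor_kcal, ceiling_kcal) {
  validate_quiz(quiz, floor_kcal, ceiling_kcal)
  attr(quiz, "estimate_floor_kcal") <- floor_kcal
  attr(quiz, "estimate_ceiling_kcal") <- ceiling_kcal
  class(quiz) <- unique(c("quiz_spec", class(quiz)))
  quiz
}

validate_quiz <- function(quiz, floor_kcal, ceiling_kcal) {
  known_types <- c("dairy", "fruit", "grain", "meat", "vegetable", "mixed")
  bad_type <- which(!quiz$food_type %in% known_types)
  if (length(bad_type) > 0) {
    abort(sprintf("quiz: unknown food type in row(s) %s",
                  paste(bad_type, collapse = ", ")))
  }
  bad_energy <- which(!is.finite(quiz$energy_kcal) | quiz$energy_kcal <= 0)
  if (length(bad_energy) > 0) {
    abort(sprintf("quiz: non-positive energy_kcal in row(s) %s",
                  paste(bad_energy, collapse = ", ")))
  }
  bad_mass <- which(!is.finite(quiz$mass_g) | quiz$mass_g <= 0)
  if (length(bad_mass) > 0) {
    abort(sprintf("quiz: non-positive mass_g in row(s) %s",
                  paste(bad_mass, collapse = ", ")))
  }
  dup <- quiz$food_id[duplicated(quiz$food_id)]
  if (length(dup) > 0) {
    abort(sprintf("quiz: duplicate food_id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  if (!(ceiling_kcal > floor_kcal)) {
    abort("quiz: estimate ceiling must exceed floor")
  }
  invisible(quiz)
}

#' @rdname load_quiz
#' @param quiz A `quiz_spec` tibble.
#' @export
quiz_floor <- function(quiz) attr(quiz, "estimate_floor_kcal") %||% 50

#' @rdname load_quiz
#' @export
quiz_ceiling <- function(quiz) attr(quiz, "estimate_ceiling_kcal") %||% 800

#' Energy density of quiz foods
#'
#' Energy density is energy per unit mass, kcal/g. In the packaged quiz it
#' spans roughly 0.17 kcal/g (broccoli, cauliflower) to 3.9 kcal/g (cheddar
#' cheese), and is strongly inversely correlated with portion mass.
#'
#' @param quiz A `quiz_spec` tibble (or any data frame with `energy_kcal` and
#'   `mass_g` columns).
#' @return Numeric vector of kcal/g, one value per row.
#' @export
#' @examples
#' quiz <- load_quiz("table1")
#' energy_density(quiz)[quiz$food_id == "cauliflower"]  # 0.25 kcal/g
energy_density <- function(quiz) {
  assert_columns(quiz, c("energy_kcal", "mass_g"), "quiz")
  quiz$energy_kcal / quiz$mass_g
}

#' Export a quiz specification as JSON
#'
#' @param quiz A `quiz_spec` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quiz_json <- function(quiz, path) {
  obj <- list(
    estimate_floor_kcal = quiz_floor(quiz),
    estimate_ceiling_kcal = quiz_ceiling(quiz),
    foods = as.data.frame(quiz)
  )
  write_json_stable(obj, path)
}
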