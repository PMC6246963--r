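#' Quality-control filters for participants and responses
#'
#' Participant-level rule: remove participants reporting a BMI below 15 or
#' above 50 kg/m^2 (implausible values), participants with no reported BMI,
#' and participants who did not report their gender. Response-level rule:
#' remove estimates below the quiz floor or above the ceiling (50 and 800
#' kcal for the packaged quiz). All rules are strict inequalities: BMI of
#' exactly 15 or 50 and estimates of exactly 50 or 800 kcal are retained.
#' A participant who loses some responses to the range filter keeps the rest.
#'
#' Both filters attach a `qc_report` attribute (retrieve with [qc_report()])
#' counting what was removed; [apply_qc()] runs both and merges the counts.
#'
#' @param participants Participant tibble.
#' @param responses Response tibble.
#' @param quiz A `quiz_spec` (supplies floor/ceiling).
#' @return The retained tibble with a `qc_report` attribute; `apply_qc()`
#'   returns a list `participants`, `responses`, `report`.
#' @name qc_filters
NULL

new_qc_report <- function(...) {
  rep_ <- list(...)
  structure(rep_, class = "qc_report")
}

#' @rdname qc_filters
#' @export
filter_participants <- function(participants) {
  bad_bmi <- is.na(participants$bmi_kg_m2) |
    participants$bmi_kg_m2 < 15 | participants$bmi_kg_m2 > 50
  bad_gender <- participants$gender == "missing" & !bad_bmi
  retained <- participants[!bad_bmi & !bad_gender, , drop = FALSE]
  report <- new_qc_report(
    n_participants_in = nrow(participants),
    n_participants_removed_bmi = sum(bad_bmi),
    n_participants_removed_gender = sum(bad_gender)
  )
  attr(retained, "qc_report") <- report
  retained
}

#' @rdname qc_filters
#' @export
filter_responses <- function(responses, quiz) {
  floor_k <- quiz_floor(quiz)
  ceil_k <- quiz_ceiling(quiz)
  out <- responses$estimate_kcal < floor_k | responses$estimate_kcal > ceil_k
  retained <- responses[!out, , drop = FALSE]
  report <- new_qc_report(
    n_responses_in = nrow(responses),
    n_responses_removed_range = sum(out)
  )
  attr(retained, "qc_report") <- report
  retained
}

#' @rdname qc_filters
#' @export
apply_qc <- function(participants, responses, quiz) {
  p <- filter_participants(participants)
  r <- filter_responses(responses, quiz)
  # responses of removed participants are dropped downstream
  r <- r[r$participant_id %in% p$participant_id, , drop = FALSE]
  report <- new_qc_report(
    n_participants_in = qc_report(p)$n_participants_in,
    n_participants_removed_bmi = qc_report(p)$n_participants_removed_bmi,
    n_participants_removed_gender = qc_report(p)$n_participants_removed_gender,
    n_responses_in = qc_report(r)$n_responses_in,
    n_responses_removed_range = qc_report(r)$n_responses_removed_range
  )
  attr(r, "qc_report") <- NULL
  attr(p, "qc_report") <- NULL
  list(participants = p, responses = r, report = report)
}

#' @rdname qc_filters
#' @param x An object carrying a QC report (a filtered tibble or the report
#'   itself).
#' @export
qc_report <- function(x) {
  if (inherits(x, "qc_report")) x else attr(x, "qc_report")
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  for (nm in names(x)) cat(sprintf("  %-32s %d\n", nm, x[[nm]]))
  invisible(x)
}
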