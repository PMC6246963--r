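#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# Inclusive tolerance for a "correct" estimate: within 20% of ground truth.
CORRECT_TOL <- 0.20

#' Age group coding used throughout the package
#'
#' The quiz collected an age *group*, not an exact age. Regressions need a
#' numeric coding, so each ordinal bin carries a midpoint (years). The exact
#' bin edges used in the original survey were not published; these bins are a
#' package convention, documented in the methods vignette.
#'
#' @return A tibble with columns `age_group` (ordered as listed) and
#'   `midpoint` (years).
#' @export
#' @examples
#' age_bins()
age_bins <- function() {
  tibble::tibble(
    age_group = c("13-17", "18-24", "25-34", "35-44", "45-54", "55-64", "65+"),
    midpoint  = c(15, 21, 29.5, 39.5, 49.5, 59.5, 70)
  )
}

age_levels <- function() age_bins()$age_group

# 0-based position of an age bin in the ordinal scale; NA-safe.
age_bin_index <- function(age_group) {
  match(age_group, age_levels()) - 1L
}

age_midpoint <- function(age_group) {
  age_bins()$midpoint[match(age_group, age_levels())]
}

# Deterministic per-stage sub-seed derived from one master seed, so that e.g.
# demographics draws are unchanged when only the noise stage is re-run.
# Kept strictly below 2^31 - 1.
sub_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) + 104729L * as.integer(stage)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# jsonlite writer with settings that make repeated runs byte-identical.
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
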