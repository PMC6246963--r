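#' Correlation between energy density and portion mass
#'
#' Pearson correlation between energy density (kcal/g) and item mass (g)
#' across the quiz foods. On the packaged 20-food quiz this is -0.70: the
#' energy-dense items were photographed in small portions and the sparse
#' ones in large portions, a confound worth knowing when reading the
#' density-bias regression.
#'
#' @param quiz A `quiz_spec` tibble.
#' @return A single correlation, or `NA` if either variable has zero
#'   variance.
#' @export
#' @examples
#' round(density_mass_correlation(load_quiz("table1")), 2)  # -0.7
density_mass_correlation <- function(quiz) {
  if (nrow(quiz) < 2) abort("need at least 2 foods")
  d <- energy_density(quiz)
  if (stats::sd(d) == 0 || stats::sd(quiz$mass_g) == 0) return(NA_real_)
  stats::cor(d, quiz$mass_g)
}

bias_model_registry <- function() {
  list(
    reference_object = list(
      outcome = "abs_e",
      fixed = "has_reference_object",
      label = "absolute error vs presence of a reference object"
    ),
    density_bias = list(
      outcome = "e",
      fixed = "density_c",
      label = "signed error vs centered (log) energy density"
    ),
    bmi_density_interaction = list(
      outcome = "eta",
      fixed = "bmi_c * density_c",
      label = "percent error vs BMI x energy density"
    ),
    demographics = list(
      outcome = "abs_e",
      fixed = "gender + age_midpoint",
      label = "absolute error vs gender and age"
    )
  )
}

#' Registered bias model names
#' @return Character vector of model names accepted by [fit_bias_model()].
#' @export
bias_models <- function() names(bias_model_registry())

# covariate assembly shared by all registered models
build_model_frame <- function(metrics, participants, quiz,
                              density_transform = "log") {
  qt <- tibble::as_tibble(quiz) %>%
    dplyr::mutate(density = energy_density(quiz)) %>%
    dplyr::mutate(density_c = if (density_transform == "log") {
      log(.data$density) - mean(log(.data$density))
    } else {
      .data$density - mean(.data$density)
    }) %>%
    dplyr::select("food_id", "has_reference_object", "density_c")
  metrics %>%
    dplyr::inner_join(qt, by = "food_id") %>%
    dplyr::inner_join(
      participants %>%
        dplyr::mutate(
          age_midpoint = age_midpoint(.data$age_group),
          bmi_c = .data$bmi_kg_m2 - 25
        ) %>%
        dplyr::select("participant_id", "gender", "age_midpoint", "bmi_c"),
      by = "participant_id"
    )
}

#' Fit a registered mixed-effects bias model
#'
#' All four registered analyses are linear mixed models with random
#' intercepts for both participants and foods, fitted by REML:
#'
#' * `"reference_object"`: `abs_e ~ has_reference_object` — does a scale
#'   object in the picture change absolute error?
#' * `"density_bias"`: `e ~ density_c` — are energy-dense foods
#'   systematically overestimated?
#' * `"bmi_density_interaction"`: `eta ~ bmi_c * density_c` — does a
#'   respondent's BMI amplify the density bias in percent error?
#' * `"demographics"`: `abs_e ~ gender + age_midpoint` — do gender and age
#'   shift error magnitude?
#'
#' Energy density enters as centered log(kcal/g) by default (`raw` is
#' available); BMI is centered at 25 kg/m^2; age enters as the numeric bin
#' midpoint. Fixed-effect p-values use the large-sample normal approximation
#' on the t statistic. `r_squared` is the squared Pearson correlation
#' between the outcome and the model's (conditional) predicted values — the
#' proportion of outcome variance described by the predictions.
#'
#' @param metrics Metric tibble from [compute_metrics()].
#' @param participants Participant tibble (post-QC).
#' @param quiz A `quiz_spec`.
#' @param model One of [bias_models()].
#' @param density_transform `"log"` (centered log density, default) or
#'   `"raw"` (centered density).
#' @return An object of class `bias_fit`; `tidy()` gives the fixed-effect
#'   table, `glance()` the one-row model summary.
#' @export
fit_bias_model <- function(metrics, participants, quiz,
                           model = c("reference_object", "density_bias",
                                     "bmi_density_interaction",
                                     "demographics"),
                           density_transform = c("log", "raw")) {
  model <- match.arg(model)
  density_transform <- match.arg(density_transform)
  spec <- bias_model_registry()[[model]]
  if (dplyr::n_distinct(metrics$participant_id) < 2 ||
      dplyr::n_distinct(metrics$food_id) < 2) {
    abort("need at least 2 participants and 2 foods")
  }
  frame <- build_model_frame(metrics, participants, quiz, density_transform)
  vars <- all.vars(stats::as.formula(paste("~", spec$fixed)))
  frame <- frame[stats::complete.cases(frame[, c(spec$outcome, vars)]), ]

  form <- stats::as.formula(paste(
    spec$outcome, "~", spec$fixed,
    "+ (1 | participant_id) + (1 | food_id)"
  ))
  notes <- character()
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(form, data = frame, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) e
    ),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      notes <<- c(notes, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(model_name = model, outcome = spec$outcome, formula = form,
           coefficients = NULL, r_squared = NA_real_, n_obs = nrow(frame),
           converged = FALSE, notes = conditionMessage(fit), fit = NULL),
      class = "bias_fit"
    ))
  }

  cc <- as.data.frame(summary(fit)$coefficients)
  coefs <- tibble::tibble(
    term = rownames(cc),
    estimate = cc[, "Estimate"],
    std.error = cc[, "Std. Error"],
    statistic = cc[, "t value"],
    p.value = 2 * stats::pnorm(-abs(cc[, "t value"]))
  )
  # boundary (singular) fits are legitimate, e.g. when a variance is truly 0
  msgs <- unlist(fit@optinfo$conv$lme4$messages) %||% character()
  hard_msgs <- msgs[!grepl("singular|boundary", msgs, ignore.case = TRUE)]
  converged <- fit@optinfo$conv$opt == 0 && length(hard_msgs) == 0

  y <- frame[[spec$outcome]]
  yhat <- stats::fitted(fit)
  r2 <- if (stats::sd(yhat) == 0) 0 else stats::cor(y, yhat)^2

  structure(
    list(model_name = model, outcome = spec$outcome, formula = form,
         label = spec$label, coefficients = coefs, r_squared = r2,
         n_obs = nrow(frame), converged = isTRUE(converged),
         notes = notes, fit = fit),
    class = "bias_fit"
  )
}

#' @exportS3Method base::print
print.bias_fit <- function(x, ...) {
  cat(sprintf("Bias model '%s' (%s), n = %d, R^2 = %.3f%s\n",
              x$model_name, deparse(x$formula), x$n_obs, x$r_squared,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (!is.null(x$coefficients)) print(as.data.frame(x$coefficients))
  invisible(x)
}

#' @rdname fit_bias_model
#' @param x A `bias_fit` object.
#' @param ... Unused.
#' @export
tidy.bias_fit <- function(x, ...) x$coefficients

#' @rdname fit_bias_model
#' @export
glance.bias_fit <- function(x, ...) {
  tibble::tibble(
    model_name = x$model_name, outcome = x$outcome,
    r_squared = x$r_squared, n_obs = x$n_obs, converged = x$converged
  )
}

#' Per-food density-bias curve
#'
#' One row per food ordered by energy density, with the mean signed error
#' and mean percent error — the tabular form of the "calorie-sparse foods
#' underestimated, calorie-rich foods overestimated" display.
#'
#' @param metrics Metric tibble from [compute_metrics()].
#' @param quiz A `quiz_spec`.
#' @return A tibble of class `density_bias_curve` with `food_id`,
#'   `energy_density`, `n`, `mean_e`, `mean_eta`.
#' @export
density_bias_curve <- function(metrics, quiz) {
  out <- tibble::tibble(
    food_id = quiz$food_id,
    energy_density = energy_density(quiz)
  ) %>%
    dplyr::left_join(
      metrics %>%
        dplyr::group_by(.data$food_id) %>%
        dplyr::summarise(n = dplyr::n(), mean_e = mean(.data$e),
                         mean_eta = mean(.data$eta), .groups = "drop"),
      by = "food_id"
    ) %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
    dplyr::arrange(.data$energy_density)
  class(out) <- c("density_bias_curve", class(out))
  out
}
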