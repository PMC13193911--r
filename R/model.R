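# Main modelling entry point: encoder + random survival forest fitted
# together on a lesion cohort, with the classic fit/predict/summary surface.

#' Fit the local-control model
#'
#' Fits the end-to-end local-control pipeline on a lesion cohort: the
#' preprocessing encoder ([fit_encoder()], learned on these rows only) and
#' the random survival forest ([fit_forest()]) for time to local failure.
#' The returned object predicts individualized local-control curves, risk
#' scores and horizon summaries, and is the model the dose-sweep engine
#' ([sweep_doses()]) interrogates.
#'
#' @param cohort A `lesion_cohort` with at least one local-failure event.
#' @param predictors Predictor specification; see [default_predictors()].
#' @param control Forest hyperparameters; see [forest_control()].
#' @param horizons Reporting horizons in months for summaries.
#' @param tau Horizon for expected local-control duration and integrated
#'   Brier score, months.
#' @return An object of class `gklc` with components `encoder`, `forest`,
#'   `horizons`, `tau`.
#' @examples
#' sim <- generate_cohort(generator_params(n_patients = 60, seed = 7))
#' fit <- gklc(sim$cohort, control = forest_control(n_trees = 50))
#' print(fit)
#' predict(fit, sim$cohort[1:2, ], type = "summary")
#' @export
gklc <- function(cohort, predictors = default_predictors(),
                 control = forest_control(), horizons = c(6, 12, 18),
                 tau = 18) {
  validate_cohort(cohort, require_events = TRUE)
  encoder <- fit_encoder(cohort, predictors)
  features <- encode_cohort(encoder, cohort)
  forest <- fit_forest(features, control)
  risk <- predict_risk(forest, features)
  apparent <- tryCatch(harrell_cindex(features$time, features$event, risk),
                       error = function(e) NA_real_)
  structure(list(encoder = encoder, forest = forest, horizons = horizons,
                 tau = tau, n = nrow(cohort),
                 n_events = sum(cohort$event == 1),
                 n_patients = length(unique(cohort$patient_id)),
                 apparent_cindex = apparent, call = match.call()),
            class = "gklc")
}

#' Predict from a fitted local-control model
#'
#' @param object A fitted [gklc()] model.
#' @param newdata A `lesion_cohort` of cases to predict.
#' @param type `"survival"` for [lc_curves], `"risk"` for ensemble-mortality
#'   scores, `"summary"` for a data frame of local-control probabilities at
#'   the model horizons plus expected local-control duration.
#' @param ... Ignored.
#' @return See `type`.
#' @export
predict.gklc <- function(object, newdata,
                         type = c("survival", "risk", "summary"), ...) {
  type <- match.arg(type)
  features <- encode_cohort(object$encoder, newdata)
  if (type == "risk") return(predict_risk(object$forest, features))
  curves <- predict_survival(object$forest, features)
  if (type == "survival") return(curves)
  out <- data.frame(patient_id = newdata$patient_id,
                    lesion_id = newdata$lesion_id,
                    stringsAsFactors = FALSE)
  for (h in object$horizons)
    out[[paste0("lc_", h, "m")]] <- lc_probability_at(curves, h)
  out$expected_lc_months <- expected_lc_duration(curves, object$tau)
  out
}

#' @export
print.gklc <- function(x, ...) {
  cat("Local-control model (random survival forest + fold-fitted encoder)\n")
  cat(sprintf("  training: %d lesions / %d patients, %d local failures\n",
              x$n, x$n_patients, x$n_events))
  cat(sprintf("  features: %d encoded columns\n", length(x$encoder$columns)))
  cat(sprintf("  horizons: %s months; tau = %g months\n",
              paste(x$horizons, collapse = "/"), x$tau))
  invisible(x)
}

#' @export
summary.gklc <- function(object, ...) {
  print(object)
  cat(sprintf("  apparent (training) C-index: %.3f -- optimistic; use\n",
              object$apparent_cindex))
  cat("  cross_validate() for leakage-resistant patient-level estimates\n")
  print(object$forest)
  invisible(object)
}

#' @export
plot.gklc <- function(x, newdata, ...) {
  plot(predict(x, newdata, type = "survival"), ...)
}
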