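# Fold-fitted preprocessing: median/mode imputation learned on training rows
# only, one-hot encoding with per-variable reference levels, removal of
# all-missing predictors, and engineered dose interactions.

#' Default predictor specification
#'
#' The treatment-time predictor set used by the local-control model: seven
#' numeric covariates, eight categoricals, and two engineered dose
#' interactions (`dose_x_vol`, `dose_x_kps`) appended by the encoder. The
#' reference-level convention drops one level for the fully observed binaries
#' and the localization codings (F for sex, "no" for the chromosome 7+/10-
#' signature, level 1 for both localization codes) while the molecular
#' fields, whose missingness is absorbed by mode imputation, emit an
#' indicator for every declared level. With every field observed this yields
#' a 28-column feature matrix.
#'
#' @return A list of predictor descriptors (`field`, `type`, and for
#'   categoricals `levels` and `reference`, where `NA` means no level is
#'   dropped).
#' @export
default_predictors <- function() {
  list(
    list(field = "age_years",   type = "numeric"),
    list(field = "coverage",    type = "numeric"),
    list(field = "isodose_pct", type = "numeric"),
    list(field = "max_gy",      type = "numeric"),
    list(field = "volume_cm3",  type = "numeric"),
    list(field = "dose_gy",     type = "numeric"),
    list(field = "kps",         type = "numeric"),
    list(field = "anatomic_loc", type = "category",
         levels = as.character(1:6), reference = "1"),
    list(field = "chr7p10q", type = "category",
         levels = c("yes", "no"), reference = "no"),
    list(field = "egfr", type = "category",
         levels = c("ampl", "mut", "unampl", "unmut"), reference = NA),
    list(field = "mgmt", type = "category",
         levels = c("methyl", "unmethyl"), reference = NA),
    list(field = "pten", type = "category",
         levels = c("mut", "umut"), reference = NA),
    list(field = "sex", type = "category",
         levels = c("M", "F"), reference = "F"),
    list(field = "tert", type = "category",
         levels = c("mut", "unmut"), reference = NA),
    list(field = "tumor_loc", type = "category",
         levels = as.character(1:3), reference = "1")
  )
}

#' Fit the preprocessing encoder on training rows
#'
#' Learns, from the training split only, the per-numeric-field median, the
#' per-categorical-field most frequent category (ties broken by declared
#' level order), and the list of predictors with no observed value (which are
#' dropped). The fitted state maps any schema-valid cohort to a fixed numeric
#' column layout; see [encode_cohort()].
#'
#' @param train A non-empty `lesion_cohort` (training rows only).
#' @param predictors Predictor specification, see [default_predictors()].
#' @return An object of class `lc_encoder`.
#' @export
fit_encoder <- function(train, predictors = default_predictors()) {
  stopifnot(is.data.frame(train))
  if (nrow(train) == 0) stop("cannot fit encoder on an empty training set")
  bad <- setdiff(vapply(predictors, `[[`, "", "field"), names(train))
  if (length(bad) > 0)
    stop("predictor spec names unknown field(s): ", paste(bad, collapse = ", "))

  medians <- list(); modes <- list(); dropped <- character(); columns <- character()
  kept <- list()
  for (p in predictors) {
    v <- train[[p$field]]
    if (all(is.na(v))) { dropped <- c(dropped, p$field); next }
    if (p$type == "numeric") {
      medians[[p$field]] <- median(v, na.rm = TRUE)
      columns <- c(columns, p$field)
    } else {
      obs <- v[!is.na(v)]
      counts <- vapply(p$levels, function(l) sum(obs == l), 0L)
      modes[[p$field]] <- p$levels[which.max(counts)]
      ref <- p$reference %||% NA
      emit <- if (is.na(ref)) p$levels else setdiff(p$levels, ref)
      columns <- c(columns, paste(p$field, emit, sep = "_"))
    }
    kept <- c(kept, list(p))
  }
  has_inter <- all(c("dose_gy", "volume_cm3", "kps") %in%
                     vapply(kept, `[[`, "", "field"))
  if (has_inter) columns <- c(columns, "dose_x_vol", "dose_x_kps")

  structure(list(predictors = kept, medians = medians, modes = modes,
                 dropped = dropped, columns = columns,
                 interactions = has_inter),
            class = "lc_encoder")
}

#' Transform a cohort into the fitted numeric feature matrix
#'
#' Applies a fitted [fit_encoder()] state: numeric fields are median-imputed,
#' categoricals are mode-imputed then expanded into indicator columns for
#' every non-reference level, and the engineered interactions `dose_x_vol`
#' and `dose_x_kps` are appended (computed from the imputed values, so they
#' track counterfactual dose injection). A categorical value outside the
#' encoder's level list maps to all-zero indicators with a warning. The
#' transform is pure: it never updates the encoder.
#'
#' @param encoder A fitted `lc_encoder`.
#' @param cohort A schema-valid `lesion_cohort`.
#' @return An object of class `lc_features`: list with numeric matrix `x`
#'   (columns exactly `encoder$columns`), `keys` (patient_id, lesion_id),
#'   and outcome vectors `time` and `event`.
#' @export
encode_cohort <- function(encoder, cohort) {
  stopifnot(inherits(encoder, "lc_encoder"), is.data.frame(cohort))
  n <- nrow(cohort)
  cols <- list()
  imputed <- list()
  for (p in encoder$predictors) {
    v <- cohort[[p$field]]
    if (p$type == "numeric") {
      v[is.na(v)] <- encoder$medians[[p$field]]
      cols[[p$field]] <- as.numeric(v)
      imputed[[p$field]] <- as.numeric(v)
    } else {
      v[is.na(v)] <- encoder$modes[[p$field]]
      unseen <- !(v %in% p$levels)
      if (any(unseen))
        warning(sprintf("field '%s': %d value(s) outside encoder levels mapped to all-zero indicators",
                        p$field, sum(unseen)))
      ref <- p$reference %||% NA
      emit <- if (is.na(ref)) p$levels else setdiff(p$levels, ref)
      for (l in emit)
        cols[[paste(p$field, l, sep = "_")]] <- as.numeric(!unseen & v == l)
    }
  }
  if (encoder$interactions) {
    inter <- add_interactions(imputed$dose_gy, imputed$volume_cm3, imputed$kps)
    cols$dose_x_vol <- inter$dose_x_vol
    cols$dose_x_kps <- inter$dose_x_kps
  }
  x <- do.call(cbind, cols[encoder$columns])
  if (n == 0) x <- matrix(numeric(0), nrow = 0, ncol = length(encoder$columns))
  colnames(x) <- encoder$columns
  stopifnot(!anyNA(x))
  structure(list(x = x,
                 keys = data.frame(patient_id = cohort$patient_id,
                                   lesion_id = cohort$lesion_id,
                                   stringsAsFactors = FALSE),
                 time = cohort$time_months,
                 event = cohort$event),
            class = "lc_features")
}

#' Engineered dose interaction terms
#'
#' @param dose_gy Prescription dose in Gy (imputed, non-missing).
#' @param volume_cm3 Enhancing volume in cm3.
#' @param kps Karnofsky Performance Status.
#' @return A list with `dose_x_vol = dose_gy * volume_cm3` and
#'   `dose_x_kps = dose_gy * kps`.
#' @export
add_interactions <- function(dose_gy, volume_cm3, kps) {
  stopifnot(!anyNA(dose_gy), !anyNA(volume_cm3), !anyNA(kps))
  list(dose_x_vol = dose_gy * volume_cm3, dose_x_kps = dose_gy * kps)
}

#' Serialize an encoder to JSON for audit
#'
#' @param encoder A fitted `lc_encoder`.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
encoder_to_json <- function(encoder, path = NULL) {
  stopifnot(inherits(encoder, "lc_encoder"))
  j <- jsonlite::toJSON(unclass(encoder), auto_unbox = TRUE, digits = NA,
                        pretty = TRUE, null = "null")
  if (!is.null(path)) { writeLines(j, path); return(invisible(j)) }
  j
}

#' @export
print.lc_encoder <- function(x, ...) {
  cat(sprintf("Preprocessing encoder: %d predictors -> %d feature columns\n",
              length(x$predictors), length(x$columns)))
  if (length(x$dropped) > 0)
    cat("Dropped (no observed values):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
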