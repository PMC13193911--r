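# End-to-end pipeline commands: simulate / validate / recommend, driven by a
# validated run configuration. Every report embeds the resolved config and
# seeds for reproducibility. A thin command-line wrapper over these
# functions ships at system.file("cli", "gksurv.R", package = "gksurv").

#' Build and validate a run configuration
#'
#' @param cohort_path Path to a cohort CSV, or `NULL` to use the generator.
#' @param generator [generator_params()] used when `cohort_path` is `NULL`
#'   (and by [run_simulate()]).
#' @param grid List of [forest_control()] hyperparameter candidates.
#' @param K_outer,K_inner Outer/inner fold counts for validation.
#' @param cv_repeats Repeated grouped-CV replicates (>1 adds a CI).
#' @param tau Evaluation horizon, months.
#' @param horizons Reporting horizons, months.
#' @param dose_min,dose_max,dose_step Feasible dose grid, Gy.
#' @param utility Dose-sweep utility: `"lc_at_12m"` or `"expected_lc"`.
#' @param tie_tol Dose tie tolerance on the utility scale.
#' @param importance_repeats Permutations per feature for importance.
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts.
#' @return A validated list of class `lc_config`.
#' @export
lc_config <- function(cohort_path = NULL, generator = generator_params(),
                      grid = list(forest_control()),
                      K_outer = 5, K_inner = 3, cv_repeats = 1,
                      tau = 18, horizons = c(6, 12, 18),
                      dose_min = 10, dose_max = 18, dose_step = 0.5,
                      utility = "lc_at_12m", tie_tol = 0.005,
                      importance_repeats = 5, seed = 1L, out_dir = ".") {
  stopifnot(inherits(generator, "generator_params"))
  if (inherits(grid, "forest_control")) grid <- list(grid)
  stopifnot(all(vapply(grid, inherits, TRUE, "forest_control")))
  stopifnot(K_outer >= 2, K_inner >= 2, cv_repeats >= 1, tau > 0,
            all(horizons > 0), tie_tol >= 0)
  utility <- match.arg(utility, c("lc_at_12m", "expected_lc"))
  build_dose_grid(dose_min, dose_max, dose_step)  # validates the range
  structure(list(cohort_path = cohort_path, generator = generator,
                 grid = grid, K_outer = K_outer, K_inner = K_inner,
                 cv_repeats = cv_repeats, tau = tau, horizons = horizons,
                 dose_min = dose_min, dose_max = dose_max,
                 dose_step = dose_step, utility = utility,
                 tie_tol = tie_tol, importance_repeats = importance_repeats,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "lc_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [lc_config()]; `generator` is a
#' mapping of [generator_params()] arguments and `grid` a list of
#' [forest_control()] argument mappings.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `lc_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  args <- raw
  if (!is.null(raw$generator))
    args$generator <- do.call(generator_params, raw$generator)
  if (!is.null(raw$grid))
    args$grid <- lapply(raw$grid, function(g) do.call(forest_control, g))
  do.call(lc_config, args)
}

.config_echo <- function(config) {
  c(unclass(config)[setdiff(names(config), c("generator", "grid"))],
    list(generator = unclass(config$generator),
         grid = lapply(config$grid, function(g) {
           g <- unclass(g)
           if (is.infinite(g$max_depth)) g$max_depth <- NULL
           g
         })))
}

.load_cohort <- function(config) {
  if (!is.null(config$cohort_path)) read_cohort(config$cohort_path)
  else generate_cohort(config$generator)$cohort
}

#' Generate and write a synthetic cohort
#'
#' Runs the generator of the config, writes `cohort.csv` and `truth.csv`
#' into the output directory, and logs a calibration summary (event
#' fraction, covariate medians) against the generator's anchors.
#'
#' @param config An [lc_config()].
#' @return Invisibly, a list with `cohort_path`, `truth_path`, and the
#'   calibration `summary`.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "lc_config"))
  sim <- generate_cohort(config$generator)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  truth_path <- file.path(config$out_dir, "truth.csv")
  write_cohort(sim$cohort, cohort_path)
  tr <- sim$truth
  tr[] <- lapply(tr, function(v) if (is.numeric(v)) sprintf("%.17g", v) else v)
  utils::write.table(tr, truth_path, sep = ",", row.names = FALSE, quote = TRUE,
                     qmethod = "double")
  s <- list(n_lesions = nrow(sim$cohort),
            n_patients = length(unique(sim$cohort$patient_id)),
            event_fraction = mean(sim$cohort$event == 1),
            median_age = median(sim$cohort$age_years, na.rm = TRUE),
            median_volume_cm3 = median(sim$cohort$volume_cm3, na.rm = TRUE),
            median_dose_gy = median(sim$cohort$dose_gy, na.rm = TRUE),
            median_kps = median(sim$cohort$kps, na.rm = TRUE))
  message(sprintf(paste0("simulated %d lesions / %d patients; event fraction ",
                         "%.3f; median dose %.1f Gy, volume %.1f cm3, age %.0f"),
                  s$n_lesions, s$n_patients, s$event_fraction,
                  s$median_dose_gy, s$median_volume_cm3, s$median_age))
  jsonlite::write_json(list(config = .config_echo(config), summary = s),
                       file.path(config$out_dir, "simulate_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort_path = cohort_path, truth_path = truth_path,
                 summary = s))
}

#' Run patient-level grouped validation and write the report
#'
#' Loads (or generates) the cohort, runs [cross_validate()] with inner-loop
#' tuning and per-fold permutation importance, and writes a JSON and a
#' plain-text report with per-fold metrics, chosen hyperparameters, the
#' importance ranking, seeds and the full resolved config.
#'
#' @param config An [lc_config()].
#' @return Invisibly, the `cv_result`.
#' @export
run_validate <- function(config) {
  stopifnot(inherits(config, "lc_config"))
  cohort <- .load_cohort(config)
  res <- cross_validate(cohort, grid = config$grid, K_outer = config$K_outer,
                        K_inner = config$K_inner, tau = config$tau,
                        seed = config$seed, repeats = config$cv_repeats,
                        importance = TRUE,
                        importance_repeats = config$importance_repeats)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = .config_echo(config),
                 pooled = res$pooled, ci = res$ci,
                 per_fold = res$per_fold,
                 importance = list(feature = res$importance$feature,
                                   delta_cindex = res$importance$delta_cindex))
  jsonlite::write_json(report, file.path(config$out_dir, "validation_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  txt <- c("Patient-level grouped cross-validation report",
           sprintf("pooled C-index: %.4f", res$pooled$cindex),
           sprintf("pooled IBS (tau=%g months): %.4f", res$tau, res$pooled$ibs),
           sprintf("CI method: %s [%.4f, %.4f] at level %.2f",
                   res$ci$method, res$ci$lower, res$ci$upper, res$ci$level),
           "", "Per fold:",
           utils::capture.output(print(res$per_fold, row.names = FALSE)),
           "", "Permutation importance (delta C-index):",
           sprintf("  %-28s %+0.4f", res$importance$feature,
                   res$importance$delta_cindex))
  writeLines(txt, file.path(config$out_dir, "validation_report.txt"))
  invisible(res)
}

#' Recommend a dose for one case and write the case report
#'
#' Fits the local-control model on the cohort (first grid entry as
#' hyperparameters), sweeps the feasible dose grid for the selected case,
#' recommends a dose, exports the ranked candidates and the recommended
#' curve, and writes a case report with local control at the configured
#' horizons, expected local-control duration, and the case's top qualitative
#' contributors (highest permutation-importance features active in the
#' case, computed on a held-out patient-level split).
#'
#' @param config An [lc_config()].
#' @param case_id Case selector `"patient_id/lesion_id"`; default first row.
#' @return Invisibly, a list with the `recommendation`, the fitted `model`
#'   and report paths.
#' @export
run_recommend <- function(config, case_id = NULL) {
  stopifnot(inherits(config, "lc_config"))
  cohort <- .load_cohort(config)
  ids <- paste(cohort$patient_id, cohort$lesion_id, sep = "/")
  if (is.null(case_id)) case_id <- ids[1]
  row <- match(case_id, ids)
  if (is.na(row))
    stop("unknown case id '", case_id, "'; available: ",
         paste(head(ids, 20), collapse = ", "),
         if (length(ids) > 20) ", ..." else "")
  ctl <- config$grid[[1]]
  ctl$seed <- .derive_seed(config$seed, 3L)
  model <- gklc(cohort, control = ctl, horizons = config$horizons,
                tau = config$tau)
  grid <- build_dose_grid(config$dose_min, config$dose_max, config$dose_step)
  sweep <- sweep_doses(model, cohort[row, , drop = FALSE], grid,
                       utility = config$utility)
  rec <- recommend(sweep, tie_tol = config$tie_tol)

  # Qualitative contributors: importance on a held-out grouped split.
  plan <- grouped_kfold(cohort$patient_id,
                        K = min(5, length(unique(cohort$patient_id))),
                        seed = .derive_seed(config$seed, 11L))
  idx <- fold_rows(plan, cohort$patient_id, 1)
  contributors <- character(0)
  if (sum(cohort$event[idx$train] == 1) > 0 && length(idx$val) > 1) {
    m_tr <- gklc(cohort[idx$train, , drop = FALSE], control = ctl,
                 horizons = config$horizons, tau = config$tau)
    imp <- tryCatch(
      permutation_importance(m_tr, cohort[idx$val, , drop = FALSE],
                             R = config$importance_repeats,
                             seed = .derive_seed(config$seed, 13L)),
      error = function(e) NULL)
    if (!is.null(imp)) {
      case_ft <- encode_cohort(model$encoder, cohort[row, , drop = FALSE])
      active <- colnames(case_ft$x)[case_ft$x[1, ] != 0]
      contributors <- head(intersect(imp$feature, active), 5)
    }
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  export_path <- file.path(config$out_dir, "dose_candidates.csv")
  export_candidates(sweep, rec, export_path)
  report <- list(config = .config_echo(config), case_id = case_id,
                 recommended_dose_gy = rec$dose_gy,
                 lc_at = as.list(rec$summary$lc_at),
                 expected_lc_months = rec$summary$expected_lc_months,
                 tie_break = rec$note,
                 top_contributors = contributors,
                 ranked = rec$ranked)
  jsonlite::write_json(report, file.path(config$out_dir, "case_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  txt <- c(sprintf("Case %s", case_id),
           sprintf("Recommended prescription dose: %.1f Gy (%s)",
                   rec$dose_gy, rec$note),
           sprintf("Local control at %s months: %s",
                   paste(config$horizons, collapse = "/"),
                   paste(sprintf("%.3f", rec$summary$lc_at), collapse = "/")),
           sprintf("Expected local control within %g months: %.2f months",
                   config$tau, rec$summary$expected_lc_months),
           if (length(contributors) > 0)
             paste("Top contributors:", paste(contributors, collapse = ", "))
           else "Top contributors: (not computed)")
  writeLines(txt, file.path(config$out_dir, "case_report.txt"))
  invisible(list(recommendation = rec, model = model,
                 export_path = export_path,
                 report_path = file.path(config$out_dir, "case_report.json")))
}
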