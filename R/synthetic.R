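# Synthetic lesion-level cohorts with a known Weibull proportional-hazards
# dose-response. Covariate marginals emulate a recurrent-glioblastoma GKRS
# cohort (median age ~60, KPS ~80, volume ~9.9 cm3, dose median 14 Gy on a
# 10-18 Gy grid, isodose ~50%, MGMT ~50/50); the hazard depends on dose,
# volume, KPS and MGMT through a linear predictor so downstream stages have
# ground truth.

#' Parameters for the synthetic cohort generator
#'
#' The latent event time of a lesion is Weibull proportional-hazards:
#' `S(t) = exp(-(t/lambda0)^shape * exp(eta))` with linear predictor
#' `eta = beta_dose*dose + beta_volume*volume + beta_kps*(kps/10) +
#' beta_mgmt*1[methylated]`. A negative `beta_dose` makes higher prescription
#' doses protective, the direction the dose-selection decision problem
#' presumes. Censoring is the minimum of an exponential follow-up time and an
#' administrative horizon. Missingness is injected completely at random per
#' field, after outcomes are generated from the complete covariates.
#'
#' Defaults are calibrated so that with `n_patients = 73` roughly a quarter
#' of lesions fail within the administrative horizon, matching the event
#' fraction of the motivating cohort (18/73).
#'
#' @param n_patients Number of patients.
#' @param prob_two_lesions Probability that a patient contributes two targets
#'   (otherwise one); all targets of a patient share patient-level covariates.
#' @param shape Weibull shape `k` (> 0); values above 1 give an increasing
#'   hazard of local failure.
#' @param lambda0 Baseline Weibull scale, months.
#' @param beta_dose Log-hazard per Gy of prescription dose (negative =
#'   protective).
#' @param beta_volume Log-hazard per cm3 of enhancing volume.
#' @param beta_kps Log-hazard per 10 KPS points.
#' @param beta_mgmt Log-hazard for MGMT-methylated vs not.
#' @param censor_rate Exponential censoring rate per month.
#' @param admin_horizon Administrative censoring horizon, months.
#' @param missing_frac Named vector of per-field missingness probabilities;
#'   unnamed fields default to 0.
#' @param scan_interval Optional imaging interval in months; when set,
#'   observed failure times are rounded up to the next scheduled scan to
#'   emulate interval-based failure ascertainment. `NULL` (default) keeps
#'   exact times.
#' @param seed Integer seed; the same parameters produce identical cohorts.
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(n_patients = 73,
                             prob_two_lesions = 0.2,
                             shape = 1.2,
                             lambda0 = 0.85,
                             beta_dose = -0.25,
                             beta_volume = 0.04,
                             beta_kps = -0.15,
                             beta_mgmt = -0.6,
                             censor_rate = 1 / 12,
                             admin_horizon = 36,
                             missing_frac = c(kps = 0.03, anatomic_loc = 0.015,
                                              tumor_loc = 0.10, coverage = 0.05,
                                              mgmt = 0.015, egfr = 0.55,
                                              pten = 0.36, tert = 0.50,
                                              chr7p10q = 0.60),
                             scan_interval = NULL,
                             seed = 1L) {
  p <- list(n_patients = as.integer(n_patients),
            prob_two_lesions = prob_two_lesions, shape = shape,
            lambda0 = lambda0, beta_dose = beta_dose,
            beta_volume = beta_volume, beta_kps = beta_kps,
            beta_mgmt = beta_mgmt, censor_rate = censor_rate,
            admin_horizon = admin_horizon, missing_frac = missing_frac,
            scan_interval = scan_interval, seed = as.integer(seed))
  if (p$n_patients < 1) stop("n_patients must be >= 1")
  if (p$prob_two_lesions < 0 || p$prob_two_lesions > 1)
    stop("prob_two_lesions must be a probability in [0, 1]")
  for (f in c("shape", "lambda0", "censor_rate", "admin_horizon"))
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) stop(f, " must be > 0")
  if (any(missing_frac < 0 | missing_frac > 1))
    stop("missing_frac entries must be probabilities in [0, 1]")
  if (!is.null(scan_interval) && scan_interval <= 0)
    stop("scan_interval must be > 0 when given")
  class(p) <- "generator_params"
  p
}

#' Sample a Weibull proportional-hazards event time
#'
#' Inverse-transform draw: `T = lambda0 * (-log(u) / exp(eta))^(1/shape)`,
#' whose survival function is `exp(-(t/lambda0)^shape * exp(eta))`.
#'
#' @param eta Linear predictor (log relative hazard); recycled.
#' @param shape Weibull shape (> 0).
#' @param lambda0 Baseline scale in months (> 0).
#' @param u Uniform draw(s) in the open interval (0, 1).
#' @return Event time(s) in months.
#' @export
sample_event_time <- function(eta, shape, lambda0, u) {
  if (shape <= 0 || lambda0 <= 0) stop("shape and lambda0 must be > 0")
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly inside (0, 1)")
  lambda0 * (-log(u) / exp(eta))^(1 / shape)
}

#' Generate a synthetic lesion-level cohort with known ground truth
#'
#' Draws patient- and lesion-level covariates matching the calibration
#' marginals (see [generator_params()]), generates latent Weibull
#' proportional-hazards failure times and exponential/administrative
#' censoring, injects completely-at-random missingness, and returns both the
#' observed cohort and the latent truth table.
#'
#' @param params A [generator_params()] object.
#' @return A list with elements `cohort` (a `lesion_cohort`) and `truth`
#'   (a data frame of per-lesion linear predictor, latent event time, censor
#'   time and generator parameter echo as attribute `params`).
#' @export
generate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  np <- params$n_patients

  # Patient-level covariates.
  age <- .rtruncnorm(np, 61.8, 11.1, 27, 82)
  sex <- ifelse(runif(np) < 0.699, "M", "F")
  kps_levels <- seq(40, 100, by = 10)
  kps <- sample(kps_levels, np, replace = TRUE,
                prob = c(0.02, 0.03, 0.08, 0.20, 0.34, 0.24, 0.09))
  mgmt <- ifelse(runif(np) < 0.51, "methyl", "unmethyl")
  egfr <- sample(c("ampl", "unampl", "mut", "unmut"), np, replace = TRUE,
                 prob = c(0.35, 0.35, 0.15, 0.15))
  pten <- ifelse(runif(np) < 0.70, "mut", "umut")
  tert <- ifelse(runif(np) < 0.90, "mut", "unmut")
  chr <- ifelse(runif(np) < 0.60, "yes", "no")
  n_lesions <- 1L + rbinom(np, 1L, params$prob_two_lesions)

  idx <- rep(seq_len(np), n_lesions)
  n <- length(idx)
  lesion_no <- sequence(n_lesions)

  # Lesion-level covariates.
  volume <- pmin(pmax(stats::rlnorm(n, log(9.9), 0.9), 0.12), 48.4)
  dose_grid <- seq(10, 18, by = 0.5)
  dose <- sample(dose_grid, n, replace = TRUE,
                 prob = stats::dnorm(dose_grid, 13.9, 1.3))
  isodose <- .rtruncnorm(n, 51.8, 7.7, 38.8, 80.9)
  max_gy <- dose / (isodose / 100)
  coverage <- stats::rbeta(n, 38, 2)
  anatomic <- sample(as.character(1:6), n, replace = TRUE,
                     prob = c(0.30, 0.11, 0.08, 0.30, 0.02, 0.19))
  tumloc <- sample(as.character(1:3), n, replace = TRUE,
                   prob = c(0.60, 0.25, 0.15))

  eta <- params$beta_dose * dose +
    params$beta_volume * volume +
    params$beta_kps * (kps[idx] / 10) +
    params$beta_mgmt * as.numeric(mgmt[idx] == "methyl")
  u <- runif(n)
  t_event <- sample_event_time(eta, params$shape, params$lambda0, u)
  t_censor <- pmin(rexp(n, params$censor_rate), params$admin_horizon)
  time_obs <- pmin(t_event, t_censor)
  event <- as.integer(t_event <= t_censor)
  if (!is.null(params$scan_interval)) {
    si <- params$scan_interval
    time_obs[event == 1L] <- ceiling(time_obs[event == 1L] / si) * si
  }
  time_obs <- pmax(time_obs, 1e-6)

  cohort <- data.frame(
    patient_id = sprintf("P%04d", idx),
    lesion_id = sprintf("L%d", lesion_no),
    age_years = age[idx], sex = sex[idx], kps = as.numeric(kps[idx]),
    volume_cm3 = volume, anatomic_loc = anatomic, tumor_loc = tumloc,
    dose_gy = dose, isodose_pct = isodose, max_gy = max_gy,
    coverage = coverage, mgmt = mgmt[idx], egfr = egfr[idx],
    pten = pten[idx], tert = tert[idx], chr7p10q = chr[idx],
    time_months = time_obs, event = event,
    stringsAsFactors = FALSE)

  # MCAR missingness, injected after outcome generation.
  mf <- params$missing_frac
  for (f in names(mf)) {
    if (!f %in% names(cohort)) next
    hit <- runif(n) < mf[[f]]
    cohort[[f]][hit] <- NA
  }

  truth <- data.frame(
    patient_id = cohort$patient_id, lesion_id = cohort$lesion_id,
    eta = eta, event_time = t_event, censor_time = t_censor,
    stringsAsFactors = FALSE)
  attr(truth, "params") <- params

  list(cohort = as_lesion_cohort(cohort, provenance = "synthetic"),
       truth = truth)
}

# Truncated-normal draw by inverse transform.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(plo + runif(n) * (phi - plo))
}
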