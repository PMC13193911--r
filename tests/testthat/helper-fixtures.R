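# Fixture builders shared across the suite. All data are generated in code.

# A small fully-observed cohort with hand-set values, n rows, one patient
# per row unless patient_of is given.
manual_cohort <- function(n = 6, time = NULL, event = NULL, dose = 14,
                          patient_of = NULL) {
  time <- time %||% seq(2, by = 3, length.out = n)
  event <- event %||% rep(c(1L, 0L), length.out = n)
  pid <- patient_of %||% sprintf("P%03d", seq_len(n))
  df <- data.frame(
    patient_id = pid,
    lesion_id = ave(pid, pid, FUN = function(z) paste0("L", seq_along(z))),
    age_years = seq(45, 75, length.out = n),
    sex = rep(c("M", "F"), length.out = n),
    kps = rep(c(80, 70, 90), length.out = n),
    volume_cm3 = seq(2, 20, length.out = n),
    anatomic_loc = rep(as.character(1:6), length.out = n),
    tumor_loc = rep(as.character(1:3), length.out = n),
    dose_gy = rep(dose, length.out = n),
    isodose_pct = rep(50, n),
    max_gy = rep(dose, length.out = n) / 0.5,
    coverage = rep(0.95, n),
    mgmt = rep(c("methyl", "unmethyl"), length.out = n),
    egfr = rep(c("ampl", "unampl", "mut", "unmut"), length.out = n),
    pten = rep(c("mut", "umut"), length.out = n),
    tert = rep(c("mut", "unmut"), length.out = n),
    chr7p10q = rep(c("yes", "no"), length.out = n),
    time_months = time,
    event = as.integer(event),
    stringsAsFactors = FALSE)
  as_lesion_cohort(df, provenance = "manual fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strong protective-dose study condition used by signal-recovery and
# dose-engine checks (event fraction ~0.35 under these betas).
strong_signal_params <- function(n_patients, seed) {
  generator_params(n_patients = n_patients, seed = seed,
                   lambda0 = 0.015, beta_dose = -0.5, beta_volume = 0.08,
                   beta_kps = -0.3, beta_mgmt = -0.8)
}

# Fully null condition: outcome independent of every covariate.
pure_noise_params <- function(n_patients, seed) {
  generator_params(n_patients = n_patients, seed = seed, lambda0 = 30,
                   beta_dose = 0, beta_volume = 0, beta_kps = 0,
                   beta_mgmt = 0)
}

# Independent brute-force C-index oracle: explicit O(n^2) pair enumeration.
brute_force_cindex <- function(times, events, risks) {
  num <- 0; den <- 0
  n <- length(times)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!(events[i] == 1 && times[i] < times[j])) next
    den <- den + 1
    if (risks[i] > risks[j]) num <- num + 1
    else if (risks[i] == risks[j]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}
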