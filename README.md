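# gksurv — local-control modelling and dose decision support for Gamma Knife radiosurgery

`gksurv` is an R package for lesion-level analysis of local tumor control
after Gamma Knife radiosurgery (GKRS) in recurrent glioblastoma, and for
model-based prescription-dose decision support. It is aimed at
radiosurgery/neuro-oncology methodologists and biostatisticians who want an
auditable, leakage-resistant pipeline from a cohort table to individualized
local-control predictions and a recommended dose.

## What it computes

**Model.** Time from GKRS to radiographically documented local failure is
right-censored at last imaging. A random survival forest is fitted on
treatment-time features (clinical, tumor, plan and molecular covariates plus
the engineered interactions dose×volume and dose×KPS): bootstrap trees split
by the standardized two-group log-rank statistic (O−E)²/V, leaves carry
Nelson–Aalen cumulative hazards Ĥ(t) = Σ dᵢ/nᵢ on the shared event-time
grid, and a case's local-control curve is S(t) = exp(−H̄(t)) with H̄ the
tree-averaged cumulative hazard. The risk score is the ensemble mortality
Σₜ H̄(t).

**Validation.** Patient-level grouped K-fold cross-validation (all targets
of a patient on one side of every split) with fold-fitted
imputation/encoding, inner-loop hyperparameter search, Harrell's C-index,
the IPCW integrated Brier score over a configurable horizon (default 18
months) using the training-fold censoring distribution, permutation
importance by ΔC-index, and cluster-bootstrap / repeated-CV confidence
intervals.

**Dose engine.** For one case, candidate prescription doses on a feasible
grid (default 10–18 Gy by 0.5) are injected counterfactually — interactions
and the maximum dose (dose / isodose fraction) are recomputed, coverage is
frozen — and scored by predicted local control at 12 months or expected
local-control duration (restricted mean ∫₀^τ S). The recommended dose is the
lowest candidate within a tie tolerance (default 0.005) of the best utility.

**Synthetic cohorts.** A generator with Weibull proportional-hazards ground
truth, T = λ₀(−log U / e^η)^{1/k} with
η = β_dose·dose + β_vol·vol + β_KPS·KPS/10 + β_MGMT·1[methyl], emulates a
recurrent-GBM GKRS cohort (median age 60, KPS 80, volume 9.9 cm³, dose 14 Gy
on a 10–18 grid, ~25% failures at defaults) with clustered lesions, censoring
and per-field missingness — so every stage is testable without patient data.

## Worked example

```r
library(gksurv)

# a synthetic cohort with a strong protective dose effect
params <- generator_params(n_patients = 200, seed = 11, lambda0 = 0.015,
                           beta_dose = -0.5, beta_volume = 0.08,
                           beta_kps = -0.3, beta_mgmt = -0.8)
sim <- generate_cohort(params)
print(sim$cohort)
#> Lesion-level cohort: 242 targets, 200 patients, 88 local failures (36.4%)
#> Provenance: synthetic
#> Follow-up: median 4.8 months; dose: median 14.0 Gy (range 10.0-17.5)

# leakage-resistant performance estimate
cv <- cross_validate(sim$cohort, grid = list(forest_control(n_trees = 150)),
                     K_outer = 5, seed = 11)
print(cv)
#> Patient-level grouped 5-fold cross-validation (1 repeat)
#>   pooled C-index: 0.732   pooled IBS (tau=18): 0.170

# fit on the full cohort and sweep doses for one case
fit <- gklc(sim$cohort, control = forest_control(n_trees = 200,
                                                 min_samples_leaf = 10,
                                                 seed = 3))
rec <- recommend(sweep_doses(fit, sim$cohort[1, , drop = FALSE],
                             build_dose_grid()))
print(rec)
#> Recommended prescription dose for P0001/L1: 17.0 Gy (lc_at_12m; 3
#> candidate(s) within tie_tol=0.005 of the maximum; lowest dose preferred)
#> Case summary (dose 17.0 Gy):
#>   local control at 6 months: 0.644
#>   local control at 12 months: 0.476
#>   local control at 18 months: 0.452
#>   expected local control within 18 months: 10.45 months
```

The pooled C-index of 0.73 says the forest correctly orders 73% of
comparable validation pairs by failure time under this strong simulated dose
effect; the IBS of 0.17 is the time-averaged censoring-weighted squared
error of the predicted curves over 18 months. The case report reads as: at
the recommended 17 Gy this target's predicted probability of remaining
controlled is 64%/48%/45% at 6/12/18 months, with 10.5 expected months of
local control within the 18-month window; two higher/equal-utility doses
were within the 0.005 tie tolerance and the lowest was preferred.

End-to-end runs (simulate → validate → recommend, with JSON/text reports)
are available as `run_simulate()` / `run_validate()` / `run_recommend()`
driven by `lc_config()` or a YAML/JSON config, and as a thin CLI at
`inst/cli/gksurv.R`.

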