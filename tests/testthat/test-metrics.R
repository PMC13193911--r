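test_that("C-index handles the canonical small cases", {
  expect_equal(harrell_cindex(c(5, 10), c(1, 1), c(2, 1)), 1)
  expect_equal(harrell_cindex(c(5, 10), c(1, 1), c(1, 2)), 0)
  expect_equal(harrell_cindex(c(5, 10, 15), c(1, 1, 0), c(3, 3, 3)), 0.5)
  # censored-first subjects contribute no comparable pairs
  expect_error(harrell_cindex(c(5, 10), c(0, 0), c(1, 2)), "no comparable")
  # tied event times are not comparable
  expect_error(harrell_cindex(c(5, 5), c(1, 1), c(1, 2)), "no comparable")
})

test_that("C-index equals exhaustive pair enumeration and is rank-invariant", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    times <- sample(1:15, n, replace = TRUE) + runif(n) * (rep %% 2)
    events <- rbinom(n, 1, 0.5)
    if (sum(events) == 0) events[1] <- 1
    risks <- sample(1:6, n, replace = TRUE)
    ours <- try(harrell_cindex(times, events, risks), silent = TRUE)
    ref <- try(brute_force_cindex(times, events, risks), silent = TRUE)
    if (inherits(ref, "try-error")) {
      expect_true(inherits(ours, "try-error"))
    } else {
      expect_equal(ours, ref)
      expect_equal(harrell_cindex(times, events, exp(risks)), ref)
    }
  }
})

test_that("censoring KM matches hand product-limit tables", {
  # no censored observations: G identically 1
  G <- km_censoring(c(1, 2, 3), c(1, 1, 1))
  expect_equal(eval_step(G, c(0.5, 1, 2, 3, 9)), rep(1, 5))
  # two subjects, first censored: G(1) = 1/2, constant thereafter
  G <- km_censoring(c(1, 2), c(0, 1))
  expect_equal(eval_step(G, 1), 0.5)
  expect_equal(eval_step(G, 5), 0.5)
  expect_equal(eval_step(G, 1, left = TRUE), 1)
  # six-subject manual table: censorings at 1, 2, 3, 5
  G <- km_censoring(c(1, 2, 2, 3, 4, 5), c(0, 1, 0, 0, 1, 0))
  expect_equal(eval_step(G, 1), 5 / 6)
  expect_equal(eval_step(G, 2), 5 / 6 * 4 / 5)
  expect_equal(eval_step(G, 2, left = TRUE), 5 / 6)
  expect_equal(eval_step(G, 3), 2 / 3 * 2 / 3)
  expect_equal(eval_step(G, 4.5), 4 / 9)
  expect_equal(eval_step(G, 5), 0)
})

test_that("Brier score: perfect and constant predictors, no censoring", {
  times <- c(2, 4, 6, 8); events <- c(1, 1, 0, 0)
  # evaluate before any censoring occurs so weights are all 1
  G <- km_censoring(times, events)
  t0 <- 5
  # perfect: S=0 for prior failures, 1 for survivors
  perfect <- lc_curves(c(2, 4), rbind(c(0, 0), c(1, 0), c(1, 1), c(1, 1)))
  expect_equal(brier_score(t0, perfect, times, events, G), 0)
  const <- lc_curves(c(2, 4), matrix(0.5, 4, 2))
  expect_equal(brier_score(t0, const, times, events, lc_stepfun(numeric(0), numeric(0))),
               0.25)
})

test_that("IPCW Brier equals an independently expanded weighted sum on a censored fixture", {
  times <- c(2, 3, 5, 7, 8, 10, 11, 13)
  events <- c(1, 0, 1, 1, 0, 1, 0, 1)
  grid <- c(2, 5, 7, 10, 13)
  set.seed(42)
  surv <- t(apply(matrix(runif(8 * 5), 8), 1, function(r) rev(sort(r))))
  curves <- lc_curves(grid, surv)
  G <- km_censoring(times, events)
  t0 <- 9
  # independent expansion with its own KM arithmetic
  km_manual <- function(tt) {
    cens_t <- c(3, 8, 11)
    atrisk <- vapply(cens_t, function(u) sum(times >= u), 0)
    g <- cumprod(1 - 1 / atrisk)
    if (tt < cens_t[1]) 1 else g[max(which(cens_t <= tt))]
  }
  s_at <- function(i, tt) { k <- findInterval(tt, grid); if (k == 0) 1 else surv[i, k] }
  total <- 0
  for (i in 1:8) {
    if (times[i] <= t0 && events[i] == 1)
      total <- total + s_at(i, t0)^2 / km_manual(times[i] - 1e-9)
    else if (times[i] > t0)
      total <- total + (1 - s_at(i, t0))^2 / km_manual(t0)
  }
  expect_equal(brier_score(t0, curves, times, events, G), total / 8)
})

test_that("with G = 1 the Brier score is the unweighted mean squared error", {
  set.seed(43)
  n <- 20
  times <- rexp(n, 0.1); events <- rep(1L, n)
  grid <- sort(unique(times))
  surv <- t(apply(matrix(runif(n * length(grid)), n), 1, function(r) rev(sort(r))))
  curves <- lc_curves(grid, surv)
  G1 <- lc_stepfun(numeric(0), numeric(0))
  t0 <- median(times)
  s_t <- lc_probability_at(curves, t0)
  y <- as.numeric(times > t0)
  mse <- mean(ifelse(times <= t0, s_t^2, (1 - s_t)^2))
  expect_equal(brier_score(t0, curves, times, events, G1), mse)
  expect_equal(mse, mean((y - s_t)^2))
})

test_that("a zero censoring weight raises a singularity error naming the time", {
  G <- km_censoring(c(1, 3), c(1, 0))   # G(3) = 0
  curves <- lc_curves(c(1, 2), matrix(c(0.9, 0.8), 1))
  expect_error(brier_score(3.5, curves, 4, 0L, G), "zero at time 3.5")
})

test_that("integrated Brier score normalizes and integrates exactly on step fixtures", {
  # constant BS = b on [0, tau] integrates to b (curve grid includes 0 so the
  # constant predictor applies from the origin)
  times <- c(2, 4, 6, 8); events <- rep(1L, 4)
  const <- lc_curves(c(0, 4), matrix(0.5, 4, 2))
  G1 <- lc_stepfun(numeric(0), numeric(0))
  expect_equal(integrated_brier(const, times, events, G1, tau = 7), 0.25)
  # doubling the integration grid changes nothing when curves step on it
  ib <- integrated_brier(const, times, events, G1, tau = 8)
  fine <- sort(unique(c(0, times, seq(0, 8, by = 0.25), 8)))
  bs <- vapply(fine, function(t) brier_score(t, const, times, events, G1), 0)
  ib_fine <- sum(diff(fine) * (head(bs, -1) + bs[-1]) / 2) / 8
  expect_lt(abs(ib - ib_fine), 1e-9)
})

test_that("an uninformative forest scores near the KM baseline IBS on null data", {
  co <- generate_cohort(pure_noise_params(120, seed = 61))$cohort
  half <- floor(nrow(co) / 2)
  tr <- co[1:half, ]; va <- co[(half + 1):nrow(co), ]
  enc <- fit_encoder(tr)
  f <- fit_forest(encode_cohort(enc, tr),
                  forest_control(n_trees = 150, min_samples_leaf = 15,
                                 min_samples_split = 30, seed = 62))
  fva <- encode_cohort(enc, va)
  G <- km_censoring(tr$time_months, tr$event)
  ibs_forest <- integrated_brier(predict_survival(f, fva), fva$time, fva$event,
                                 G, tau = 18)
  km <- survival::survfit(survival::Surv(tr$time_months, tr$event) ~ 1)
  grid <- sort(unique(tr$time_months[tr$event == 1]))
  s_km <- vapply(grid, function(g) min(km$surv[km$time <= g], 1), 0)
  base_curves <- lc_curves(grid, matrix(rep(s_km, each = nrow(va)), nrow(va)))
  ibs_km <- integrated_brier(base_curves, fva$time, fva$event, G, tau = 18)
  expect_lt(abs(ibs_forest - ibs_km), 0.05)
})
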