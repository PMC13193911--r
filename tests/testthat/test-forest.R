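make_features <- function(n = 60, p = 4, seed = 1, signal = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- if (signal) x[, 1] else rep(0, n)
  time <- rexp(n, 0.1 * exp(eta))
  cens <- rexp(n, 0.05)
  list(x = x, time = pmin(time, cens), event = as.integer(time <= cens))
}

test_that("a root-leaf tree predicts the Nelson-Aalen estimator of its bootstrap sample", {
  ft <- make_features(40, seed = 2)
  ctl <- forest_control(n_trees = 1, min_samples_split = 1000, seed = 3)
  f <- fit_forest(ft, ctl)
  inbag <- f$trees[[1]]$inbag
  tt <- ft$time[inbag]; ee <- ft$event[inbag]
  na_ref <- vapply(f$grid, function(g) {
    ut <- sort(unique(tt[ee == 1 & tt <= g]))
    sum(vapply(ut, function(u) sum(tt == u & ee == 1) / sum(tt >= u), 0))
  }, 0)
  curves <- predict_survival(f, ft)
  expect_equal(curves$surv[1, ], exp(-na_ref), tolerance = 1e-12)
  # single-leaf forest: every row gets the same curve and risk
  expect_equal(apply(curves$surv, 2, function(col) length(unique(col))),
               rep(1, length(f$grid)))
  expect_length(unique(predict_risk(f, ft)), 1)
})

test_that("fits are deterministic in the seed and vary across seeds", {
  ft <- make_features(50, seed = 4)
  f1 <- fit_forest(ft, forest_control(n_trees = 10, seed = 7))
  f2 <- fit_forest(ft, forest_control(n_trees = 10, seed = 7))
  expect_identical(f1$trees, f2$trees)
  f3 <- fit_forest(ft, forest_control(n_trees = 10, seed = 8))
  expect_false(identical(f1$trees[[1]]$inbag, f3$trees[[1]]$inbag))
})

test_that("predicted curves are valid non-increasing step functions for random rows", {
  ft <- make_features(80, seed = 5)
  f <- fit_forest(ft, forest_control(n_trees = 30, seed = 9))
  set.seed(10)
  new <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, colnames(ft$x)))
  curves <- predict_survival(f, new)
  expect_true(all(curves$surv >= 0 & curves$surv <= 1))
  expect_true(all(curves$surv[, -1] - curves$surv[, -ncol(curves$surv)] <= 1e-12))
})

test_that("an ensemble of two identical trees predicts like either tree", {
  ft <- make_features(40, seed = 6)
  f1 <- fit_forest(ft, forest_control(n_trees = 1, seed = 11))
  f2 <- f1
  f2$trees <- c(f1$trees, f1$trees)
  f2$control$n_trees <- 2L
  expect_equal(predict_survival(f2, ft)$surv, predict_survival(f1, ft)$surv)
})

test_that("risk is the curve mass: stochastically worse rows rank higher", {
  ft <- make_features(80, seed = 12)
  f <- fit_forest(ft, forest_control(n_trees = 25, seed = 13))
  curves <- predict_survival(f, ft)
  risks <- predict_risk(f, ft)
  s <- curves$surv
  checked <- 0
  for (i in 1:30) for (j in 1:30) {
    if (i == j) next
    if (all(s[i, ] <= s[j, ]) && any(s[i, ] < s[j, ])) {
      expect_gt(risks[i], risks[j]); checked <- checked + 1
    }
  }
  expect_gt(checked, 0)
  # when curves do not cross, risk ranking equals ranking by 1 - S(tau)
  tau <- median(f$grid)
  noncross <- which(!duplicated(round(s %*% rep(1, ncol(s)), 10)))[1:10]
  sub <- s[noncross, , drop = FALSE]
  ok <- outer(seq_len(10), seq_len(10), Vectorize(function(a, b)
    all(sub[a, ] <= sub[b, ]) || all(sub[a, ] >= sub[b, ])))
  if (all(ok)) {
    r1 <- rank(risks[noncross])
    r2 <- rank(1 - lc_probability_at(lc_curves(f$grid, sub), tau))
    expect_true(cor(r1, r2, method = "spearman") > 0.99)
  }
})

test_that("prediction demands the training column layout", {
  ft <- make_features(30, seed = 14)
  f <- fit_forest(ft, forest_control(n_trees = 5, seed = 15))
  bad <- ft$x[, c(2, 1, 3, 4)]
  expect_error(predict_survival(f, bad), "column layout")
})

test_that("fitting with zero events errors", {
  ft <- make_features(20, seed = 16)
  ft$event <- rep(0L, 20)
  expect_error(fit_forest(ft), "zero events")
})

test_that("a JSON-serialized forest re-predicts exactly", {
  ft <- make_features(40, seed = 17)
  f <- fit_forest(ft, forest_control(n_trees = 8, seed = 18))
  path <- withr::local_tempfile(fileext = ".json")
  forest_to_json(f, path)
  back <- forest_from_json(path)
  expect_equal(predict_survival(back, ft)$surv, predict_survival(f, ft)$surv)
  expect_equal(predict_risk(back, ft), predict_risk(f, ft))
})

test_that("held-out discrimination on strong-signal cohorts matches an independent forest", {
  tr <- generate_cohort(strong_signal_params(150, seed = 51))$cohort
  te <- generate_cohort(strong_signal_params(80, seed = 52))$cohort
  enc <- fit_encoder(tr)
  ftr <- encode_cohort(enc, tr); fte <- encode_cohort(enc, te)
  f <- fit_forest(ftr, forest_control(n_trees = 150, seed = 6))
  c_ours <- harrell_cindex(fte$time, fte$event, predict_risk(f, fte))
  expect_gt(c_ours, 0.65)
  rg <- ranger::ranger(dependent.variable.name = "time",
                       status.variable.name = "status",
                       data = data.frame(ftr$x, time = ftr$time,
                                         status = ftr$event),
                       num.trees = 150, seed = 6)
  risk_rg <- rowSums(predict(rg, data.frame(fte$x))$chf)
  c_rg <- harrell_cindex(fte$time, fte$event, risk_rg)
  expect_gt(c_rg, 0.65)
  expect_lt(abs(c_ours - c_rg), 0.1)
})
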