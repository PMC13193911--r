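test_that("grouped folds partition patients exactly", {
  ids <- rep(sprintf("P%02d", 1:10), each = 2)
  plan <- grouped_kfold(ids, K = 5, seed = 3)
  expect_length(plan$folds, 5)
  expect_true(all(lengths(plan$folds) == 2))
  expect_setequal(unlist(plan$folds), unique(ids))
  expect_equal(anyDuplicated(unlist(plan$folds)), 0)
})

test_that("all lesions of a patient stay in one fold", {
  ids <- c(rep("A", 3), "B", "C", "D", "E")
  plan <- grouped_kfold(ids, K = 3, seed = 1)
  rows <- fold_rows(plan, ids, which(vapply(plan$folds, function(f) "A" %in% f, TRUE)))
  expect_true(all(which(ids == "A") %in% rows$val))
  expect_false(any(which(ids == "A") %in% rows$train))
})

test_that("fold plans are deterministic and validate K", {
  ids <- sprintf("P%02d", 1:12)
  expect_identical(grouped_kfold(ids, 4, seed = 9), grouped_kfold(ids, 4, seed = 9))
  expect_false(identical(grouped_kfold(ids, 4, seed = 9)$folds,
                         grouped_kfold(ids, 4, seed = 10)$folds))
  expect_error(grouped_kfold(ids, 13, seed = 1), "exceeds")
})

test_that("no patient ever spans folds across many random plans", {
  set.seed(77)
  for (s in 1:50) {
    n_pat <- sample(6:40, 1)
    ids <- sample(sprintf("P%02d", seq_len(n_pat)), n_pat * 2, replace = TRUE)
    K <- sample(2:min(5, length(unique(ids))), 1)
    plan <- grouped_kfold(ids, K, seed = s)
    expect_setequal(unlist(plan$folds), unique(ids))
    expect_equal(anyDuplicated(unlist(plan$folds)), 0)
    expect_true(all(lengths(plan$folds) >= 1))
  }
})

test_that("cross-validation metrics come from validation rows with training-only fitting", {
  sim <- generate_cohort(generator_params(n_patients = 60, seed = 71))
  cv <- cross_validate(sim$cohort, grid = list(forest_control(n_trees = 40)),
                       K_outer = 3, seed = 72)
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(sum(cv$per_fold$n_val), nrow(sim$cohort))
  expect_true(all(is.finite(cv$per_fold$cindex) | is.na(cv$per_fold$cindex)))
  expect_identical(cv$ci$method, "none")
  # deterministic end to end
  cv2 <- cross_validate(sim$cohort, grid = list(forest_control(n_trees = 40)),
                        K_outer = 3, seed = 72)
  expect_equal(cv$per_fold, cv2$per_fold)
})

test_that("mutating validation rows never changes fold-fitted components", {
  sim <- generate_cohort(generator_params(n_patients = 50, seed = 73))
  co <- sim$cohort
  plan <- grouped_kfold(co$patient_id, 5, seed = 74)
  idx <- fold_rows(plan, co$patient_id, 1)
  train <- co[idx$train, ]
  enc1 <- fit_encoder(train)
  f1 <- fit_forest(encode_cohort(enc1, train), forest_control(n_trees = 20, seed = 75))
  G1 <- km_censoring(train$time_months, train$event)
  # mutate the validation block arbitrarily
  co$volume_cm3[idx$val] <- 999
  co$time_months[idx$val] <- co$time_months[idx$val] * 10
  train2 <- co[idx$train, ]
  enc2 <- fit_encoder(train2)
  f2 <- fit_forest(encode_cohort(enc2, train2), forest_control(n_trees = 20, seed = 75))
  G2 <- km_censoring(train2$time_months, train2$event)
  expect_identical(enc1, enc2)
  expect_identical(f1$trees, f2$trees)
  expect_identical(G1, G2)
})

test_that("inner grid search picks a configuration and labels it per fold", {
  sim <- generate_cohort(strong_signal_params(60, seed = 76))
  grid <- list(forest_control(n_trees = 30, max_depth = 2),
               forest_control(n_trees = 30))
  cv <- cross_validate(sim$cohort, grid = grid, K_outer = 2, K_inner = 2,
                       seed = 77)
  expect_true(all(grepl("trees=30", cv$per_fold$hp)))
})

test_that("repeated grouped CV yields an ordered interval with a method tag", {
  sim <- generate_cohort(generator_params(n_patients = 50, seed = 78))
  cv <- cross_validate(sim$cohort, grid = list(forest_control(n_trees = 30)),
                       K_outer = 3, seed = 79, repeats = 3)
  expect_identical(cv$ci$method, "repeated_grouped_cv")
  expect_lte(cv$ci$lower, cv$ci$upper)
  expect_gte(cv$pooled$cindex, cv$ci$lower - 0.15)
})

test_that("cluster bootstrap keeps lesions together and gives sane intervals", {
  co <- generate_cohort(generator_params(n_patients = 40, seed = 81,
                                         prob_two_lesions = 0.5))$cohort
  # constant metric: zero-width interval
  ci0 <- cluster_bootstrap_ci(co, function(d) 42, B = 20, seed = 82)
  expect_equal(ci0$lower, 42); expect_equal(ci0$upper, 42)
  # lesions of one patient travel together
  probe <- cluster_bootstrap_ci(co, function(d) {
    per <- tapply(d$lesion_id, d$patient_id, length)
    orig <- tapply(co$lesion_id, co$patient_id, length)
    base <- sub("#.*$", "", names(per))
    if (any(per != orig[base])) stop("cluster broken")
    mean(d$event)
  }, B = 25, seed = 83)
  expect_true(is.finite(probe$lower))
  # ordered bounds containing the point estimate across random fixtures
  set.seed(84)
  for (s in 1:30) {
    cs <- generate_cohort(generator_params(n_patients = 25, seed = 900 + s))$cohort
    stat <- function(d) mean(d$time_months)
    ci <- cluster_bootstrap_ci(cs, stat, B = 60, level = 0.9, seed = s)
    expect_lte(ci$lower, ci$upper)
    expect_gte(stat(cs), ci$lower - 1e-9)
    expect_lte(stat(cs), ci$upper + 1e-9)
  }
})

test_that("dropped bootstrap replicates are counted and reported", {
  co <- generate_cohort(generator_params(n_patients = 20, seed = 85))$cohort
  k <- 0
  flaky <- function(d) { k <<- k + 1; if (k %% 3 == 0) stop("undefined") else mean(d$event) }
  expect_message(ci <- cluster_bootstrap_ci(co, flaky, B = 30, seed = 86),
                 "dropped")
  expect_equal(ci$dropped, 10)
  expect_equal(ci$B_used, 20)
})

test_that("permutation importance: constant feature scores exactly zero, fixed seed reproduces", {
  set.seed(91)
  n <- 60
  x <- cbind(signal = rnorm(n), flat = rep(1, n), noise = rnorm(n))
  time <- rexp(n, 0.1 * exp(x[, "signal"]))
  cens <- rexp(n, 0.06)
  ft <- list(x = x, time = pmin(time, cens), event = as.integer(time <= cens))
  f <- fit_forest(ft, forest_control(n_trees = 60, seed = 92))
  imp1 <- permutation_importance(f, ft, R = 5, seed = 93)
  imp2 <- permutation_importance(f, ft, R = 5, seed = 93)
  expect_identical(imp1, imp2)
  expect_equal(imp1$delta_cindex[imp1$feature == "flat"], 0)
  expect_gt(imp1$delta_cindex[imp1$feature == "signal"],
            imp1$delta_cindex[imp1$feature == "noise"])
})
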