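# Leakage-resistant validation: patient-level grouped K-fold plans, nested
# cross-validation with inner-loop tuning, cluster-bootstrap confidence
# intervals, and permutation importance by delta C-index.

#' Patient-level grouped K-fold plan
#'
#' Shuffles the distinct patients with the given seed and deals them into K
#' near-equal folds, so that all lesions of a patient land in exactly one
#' fold — the grouping that keeps correlated targets of one patient off both
#' sides of any split.
#'
#' @param patient_ids Vector of patient identifiers, one per lesion row.
#' @param K Number of folds (at most the number of distinct patients).
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: list with `folds` (list of K
#'   patient-id vectors), `K`, `seed`.
#' @export
grouped_kfold <- function(patient_ids, K, seed = 1L) {
  patients <- unique(as.character(patient_ids))
  if (K > length(patients))
    stop("K (", K, ") exceeds the number of distinct patients (",
         length(patients), ")")
  if (K < 2) stop("K must be at least 2")
  set.seed(seed)
  shuffled <- sample(patients)
  assign <- rep_len(seq_len(K), length(patients))
  folds <- split(shuffled, assign)
  names(folds) <- NULL
  structure(list(folds = folds, K = K, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Row indices of one fold of a plan
#'
#' @param plan A [grouped_kfold()] plan.
#' @param patient_ids The per-row patient ids the plan was built from.
#' @param k Fold number.
#' @return List with integer vectors `train` and `val`.
#' @export
fold_rows <- function(plan, patient_ids, k) {
  stopifnot(inherits(plan, "fold_plan"), k >= 1, k <= plan$K)
  val <- which(as.character(patient_ids) %in% plan$folds[[k]])
  list(train = setdiff(seq_along(patient_ids), val), val = val)
}

.derive_seed <- function(...) {
  as.integer(sum(c(...) * c(1, 131, 8191, 524287)[seq_along(c(...))]) %% 2147483647L)
}

#' Patient-level grouped cross-validation with inner-loop tuning
#'
#' Per outer fold: the encoder is fitted on the training rows only; when the
#' hyperparameter grid has more than one candidate, an inner grouped K-fold
#' grid search picks the configuration maximizing mean inner C-index; the
#' forest is refitted on the full outer-training split; and the validation
#' rows are scored by Harrell's C-index and the integrated Brier score, with
#' the censoring distribution estimated from the outer-training split. The
#' pooled estimate is the mean over folds. With `repeats > 1` the whole
#' procedure is repeated with fresh fold plans and a percentile interval
#' across repeats is reported (method tag `"repeated_grouped_cv"`).
#'
#' @param cohort A `lesion_cohort`.
#' @param grid List of [forest_control()] candidates (see [default_grid()]).
#' @param K_outer,K_inner Outer and inner fold counts.
#' @param tau Integrated-Brier horizon, months.
#' @param seed Integer seed controlling fold plans and forest fits.
#' @param predictors Predictor specification.
#' @param repeats Number of repeated grouped-CV replicates.
#' @param importance If `TRUE`, per-fold permutation importance on the
#'   validation block is computed and averaged (see
#'   [permutation_importance()]).
#' @param importance_repeats Permutations per feature when `importance`.
#' @param level Confidence level for the repeated-CV interval.
#' @return An object of class `cv_result`: `per_fold` data frame, `pooled`
#'   list (`cindex`, `ibs`), `ci` (bounds, level, method tag), `importance`
#'   (or `NULL`), `tau`, `seed`.
#' @export
cross_validate <- function(cohort, grid = list(forest_control()),
                           K_outer = 5, K_inner = 3, tau = 18, seed = 1L,
                           predictors = default_predictors(), repeats = 1,
                           importance = FALSE, importance_repeats = 5,
                           level = 0.95) {
  validate_cohort(cohort, require_events = TRUE)
  if (inherits(grid, "forest_control")) grid <- list(grid)
  per_fold <- list()
  imp_acc <- list()
  for (r in seq_len(repeats)) {
    plan <- grouped_kfold(cohort$patient_id, K_outer, seed = .derive_seed(seed, r))
    for (k in seq_len(K_outer)) {
      idx <- fold_rows(plan, cohort$patient_id, k)
      train <- cohort[idx$train, , drop = FALSE]
      val <- cohort[idx$val, , drop = FALSE]
      if (sum(train$event == 1) == 0)
        stop("fold degeneracy: outer-training split of fold ", k,
             " contains zero events; use fewer folds or a larger cohort")
      encoder <- fit_encoder(train, predictors)
      ft_train <- encode_cohort(encoder, train)
      best <- grid[[1]]
      if (length(grid) > 1) {
        scores <- .inner_grid_search(train, grid, K_inner, predictors,
                                     .derive_seed(seed, r, k))
        best <- grid[[which.max(scores)]]
      }
      ctl <- best
      ctl$seed <- .derive_seed(seed, r, k, 99L)
      forest <- fit_forest(ft_train, ctl)
      ft_val <- encode_cohort(encoder, val)
      risk <- predict_risk(forest, ft_val)
      curves <- predict_survival(forest, ft_val)
      G <- km_censoring(train$time_months, train$event)
      ci_fold <- tryCatch(harrell_cindex(ft_val$time, ft_val$event, risk),
                          error = function(e) NA_real_)
      ibs_fold <- tryCatch(
        integrated_brier(curves, ft_val$time, ft_val$event, G, tau),
        error = function(e) NA_real_)
      per_fold[[length(per_fold) + 1]] <- data.frame(
        repeat_ = r, fold = k, n_val = nrow(val),
        events_val = sum(val$event == 1),
        cindex = ci_fold, ibs = ibs_fold,
        hp = .hp_label(ctl), stringsAsFactors = FALSE)
      if (importance) {
        imp <- permutation_importance(forest, ft_val,
                                      R = importance_repeats,
                                      seed = .derive_seed(seed, r, k, 7L))
        imp_acc[[length(imp_acc) + 1]] <- setNames(imp$delta_cindex, imp$feature)
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)
  pooled_by_rep <- vapply(seq_len(repeats), function(r)
    mean(per_fold$cindex[per_fold$repeat_ == r], na.rm = TRUE), 0)
  pooled <- list(cindex = mean(per_fold$cindex, na.rm = TRUE),
                 ibs = mean(per_fold$ibs, na.rm = TRUE))
  ci <- if (repeats > 1) {
    qs <- quantile(pooled_by_rep, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE, type = 7)
    list(lower = qs[1], upper = qs[2], level = level,
         method = "repeated_grouped_cv")
  } else list(lower = NA_real_, upper = NA_real_, level = level,
              method = "none")
  imp_out <- NULL
  if (importance && length(imp_acc) > 0) {
    feats <- sort(unique(unlist(lapply(imp_acc, names))))
    mat <- do.call(rbind, lapply(imp_acc, function(v) v[feats]))
    means <- colMeans(mat, na.rm = TRUE)
    ord <- order(means, decreasing = TRUE)
    imp_out <- structure(list(feature = feats[ord],
                              delta_cindex = unname(means[ord])),
                         class = "lc_importance")
  }
  structure(list(per_fold = per_fold, pooled = pooled, ci = ci,
                 importance = imp_out, tau = tau, seed = seed,
                 K_outer = K_outer, K_inner = K_inner, repeats = repeats),
            class = "cv_result")
}

.hp_label <- function(ctl) {
  sprintf("trees=%d depth=%s leaf=%d mtry=%s",
          ctl$n_trees,
          if (is.infinite(ctl$max_depth)) "Inf" else ctl$max_depth,
          ctl$min_samples_leaf, format(ctl$max_features))
}

.inner_grid_search <- function(train, grid, K_inner, predictors, seed) {
  K_inner <- min(K_inner, length(unique(train$patient_id)))
  plan <- grouped_kfold(train$patient_id, K_inner, seed = seed)
  scores <- matrix(NA_real_, nrow = length(grid), ncol = K_inner)
  for (k in seq_len(K_inner)) {
    idx <- fold_rows(plan, train$patient_id, k)
    tr <- train[idx$train, , drop = FALSE]
    va <- train[idx$val, , drop = FALSE]
    if (sum(tr$event == 1) == 0) next
    enc <- fit_encoder(tr, predictors)
    ft_tr <- encode_cohort(enc, tr)
    ft_va <- encode_cohort(enc, va)
    for (ci in seq_along(grid)) {
      ctl <- grid[[ci]]
      ctl$seed <- .derive_seed(seed, k, ci)
      forest <- fit_forest(ft_tr, ctl)
      scores[ci, k] <- tryCatch(
        harrell_cindex(ft_va$time, ft_va$event, predict_risk(forest, ft_va)),
        error = function(e) NA_real_)
    }
  }
  rowMeans(scores, na.rm = TRUE)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Patient-level grouped %d-fold cross-validation (%d repeat%s)\n",
              x$K_outer, x$repeats, if (x$repeats > 1) "s" else ""))
  cat(sprintf("  pooled C-index: %.3f   pooled IBS (tau=%g): %.3f\n",
              x$pooled$cindex, x$tau, x$pooled$ibs))
  if (x$ci$method != "none")
    cat(sprintf("  %.0f%% CI for C-index (%s): %.3f-%.3f\n",
                100 * x$ci$level, x$ci$method, x$ci$lower, x$ci$upper))
  invisible(x)
}

#' Cluster-bootstrap percentile confidence interval
#'
#' Resamples whole patients with replacement (all lesions of a patient travel
#' together, preserving within-patient correlation), recomputes the metric on
#' each replicate cohort, and returns the percentile interval. Replicates on
#' which the metric is undefined are dropped with a logged count.
#'
#' @param cohort A `lesion_cohort`.
#' @param statistic Function taking a replicate `lesion_cohort` and returning
#'   a numeric scalar.
#' @param B Number of bootstrap replicates (>= 2).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List with `lower`, `upper`, `level`, `B_used`, `dropped`,
#'   `method = "cluster_bootstrap_percentile"`, and the replicate values.
#' @export
cluster_bootstrap_ci <- function(cohort, statistic, B = 500, level = 0.95,
                                 seed = 1L) {
  stopifnot(B >= 2, is.function(statistic))
  patients <- unique(cohort$patient_id)
  rows_of <- split(seq_len(nrow(cohort)), cohort$patient_id)
  set.seed(seed)
  vals <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    take <- sample(patients, length(patients), replace = TRUE)
    pieces <- lapply(seq_along(take), function(i) {
      rows <- cohort[rows_of[[take[i]]], , drop = FALSE]
      rows$patient_id <- sprintf("%s#%d", rows$patient_id, i)
      rows
    })
    rep_cohort <- do.call(rbind, pieces)
    class(rep_cohort) <- c("lesion_cohort", "data.frame")
    attr(rep_cohort, "provenance") <- "cluster-bootstrap replicate"
    vals[b] <- tryCatch(statistic(rep_cohort), error = function(e) NA_real_)
  }
  dropped <- sum(is.na(vals))
  if (dropped > 0)
    message("cluster_bootstrap_ci: ", dropped,
            " replicate(s) dropped (metric undefined)")
  ok <- vals[!is.na(vals)]
  if (length(ok) < 2) stop("too few valid bootstrap replicates")
  qs <- quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], level = level, B_used = length(ok),
       dropped = dropped, method = "cluster_bootstrap_percentile",
       replicates = ok)
}

#' Permutation importance by delta C-index
#'
#' For each encoded feature, its column is permuted within the validation
#' block `R` times and the validation C-index recomputed; the importance is
#' the baseline C-index minus the mean permuted C-index. The model is never
#' refitted, and training rows are never touched. A constant column has
#' importance exactly 0.
#'
#' @param model A fitted [gklc()] model or an `lc_forest`.
#' @param newdata For a `gklc` model, a `lesion_cohort` of validation cases
#'   (patients disjoint from training); for an `lc_forest`, an `lc_features`
#'   block.
#' @param R Permutations per feature.
#' @param seed Integer seed (results are reproducible).
#' @return An object of class `lc_importance`: list with `feature` and
#'   `delta_cindex`, sorted decreasing.
#' @export
permutation_importance <- function(model, newdata, R = 10, seed = 1L) {
  if (inherits(model, "gklc")) {
    features <- encode_cohort(model$encoder, newdata)
    forest <- model$forest
  } else {
    stopifnot(inherits(model, "lc_forest"))
    features <- newdata
    forest <- model
  }
  x <- features$x
  baseline <- harrell_cindex(features$time, features$event,
                             predict_risk(forest, x))
  set.seed(seed)
  delta <- setNames(numeric(ncol(x)), colnames(x))
  for (j in seq_len(ncol(x))) {
    if (length(unique(x[, j])) == 1) { delta[j] <- 0; next }
    perm_c <- numeric(R)
    for (r in seq_len(R)) {
      xp <- x
      xp[, j] <- x[sample(nrow(x)), j]
      perm_c[r] <- harrell_cindex(features$time, features$event,
                                  predict_risk(forest, xp))
    }
    delta[j] <- baseline - mean(perm_c)
  }
  ord <- order(delta, decreasing = TRUE)
  structure(list(feature = names(delta)[ord],
                 delta_cindex = unname(delta[ord]),
                 baseline_cindex = baseline),
            class = "lc_importance")
}

#' @export
print.lc_importance <- function(x, n = 10, ...) {
  cat("Permutation importance (mean decrease in C-index)\n")
  k <- min(n, length(x$feature))
  for (i in seq_len(k))
    cat(sprintf("  %-28s %+0.4f\n", x$feature[i], x$delta_cindex[i]))
  invisible(x)
}

#' @export
plot.lc_importance <- function(x, n = 15, ...) {
  k <- min(n, length(x$feature))
  idx <- rev(seq_len(k))
  barplot(x$delta_cindex[idx], names.arg = x$feature[idx], horiz = TRUE,
          las = 1, xlab = expression(Delta ~ "C-index"), ...)
  invisible(x)
}
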