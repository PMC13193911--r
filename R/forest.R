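# Random survival forest for right-censored time to local failure:
# bootstrap trees, log-rank splits, Nelson-Aalen leaves on a shared
# event-time grid, ensemble survival curves and mortality risk scores.

#' Forest hyperparameters
#'
#' @param n_trees Number of bootstrap trees.
#' @param max_depth Maximum tree depth (`Inf` = unlimited).
#' @param min_samples_split Minimum node size eligible for splitting.
#' @param min_samples_leaf Minimum rows in each child.
#' @param max_features Fraction of features tried per node (in (0, 1]) or
#'   the rule name `"sqrt"`.
#' @param seed Integer seed used when fitting.
#' @return A list of class `forest_control`.
#' @export
forest_control <- function(n_trees = 200, max_depth = Inf,
                           min_samples_split = 6, min_samples_leaf = 3,
                           max_features = 0.58, seed = 1L) {
  stopifnot(n_trees >= 1, min_samples_split >= 2, min_samples_leaf >= 1,
            is.infinite(max_depth) || max_depth >= 1)
  if (is.character(max_features)) {
    if (!identical(max_features, "sqrt"))
      stop("max_features must be a fraction in (0,1] or \"sqrt\"")
  } else stopifnot(max_features > 0, max_features <= 1)
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 min_samples_split = as.integer(min_samples_split),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 max_features = max_features, seed = as.integer(seed)),
            class = "forest_control")
}

#' Default hyperparameter tuning grid
#'
#' The inner-loop grid searched during cross-validation, spanning number of
#' trees, depth, leaf size and feature subsampling. Kept deliberately small;
#' pass any list of [forest_control()] objects to widen it.
#'
#' @param n_trees,max_depth,min_samples_leaf,max_features Vectors of values
#'   crossed into a full grid.
#' @return A list of `forest_control` objects.
#' @export
default_grid <- function(n_trees = c(200L, 500L),
                         max_depth = c(3, 5, Inf),
                         min_samples_leaf = c(3L, 5L, 10L),
                         max_features = c(0.33, 0.58, 1.0)) {
  g <- expand.grid(n_trees = n_trees, max_depth = max_depth,
                   min_samples_leaf = min_samples_leaf,
                   max_features = max_features)
  lapply(seq_len(nrow(g)), function(i)
    forest_control(n_trees = g$n_trees[i], max_depth = g$max_depth[i],
                   min_samples_split = max(2L, 2L * g$min_samples_leaf[i]),
                   min_samples_leaf = g$min_samples_leaf[i],
                   max_features = g$max_features[i]))
}

#' Two-group log-rank split statistic
#'
#' The squared standardized log-rank statistic `(O - E)^2 / V` comparing the
#' rows flagged by `left_mask` with the rest: observed minus expected events
#' in the left group summed over pooled event times, normalized by the
#' hypergeometric variance. This is the split criterion maximized by the
#' forest. Degenerate tables (a side with no at-risk subjects, or zero
#' variance) yield 0.
#'
#' @param times Observed times.
#' @param events Event indicators (1 = failure, 0 = censored).
#' @param left_mask Logical vector: membership of the left group.
#' @return A non-negative scalar.
#' @export
logrank_split_statistic <- function(times, events, left_mask) {
  stopifnot(length(times) == length(events),
            length(times) == length(left_mask))
  if (!any(left_mask) || all(left_mask)) return(0)
  .rsf_logrank_stat(as.numeric(times), as.integer(events),
                    as.logical(left_mask))
}

#' Fit a random survival forest
#'
#' Grows `n_trees` trees, each on a bootstrap sample of the rows. At every
#' node, `ceiling(max_features * p)` candidate features are drawn without
#' replacement and the split maximizing [logrank_split_statistic()] over
#' midpoint thresholds is taken (ties broken toward the lowest feature index
#' then the lowest threshold). Leaves store the Nelson-Aalen cumulative
#' hazard of their bootstrap rows on the shared grid of unique training
#' event times, so ensemble averaging happens on the hazard scale.
#'
#' @param features An `lc_features` object from [encode_cohort()], or a list
#'   with numeric matrix `x` and vectors `time`, `event`.
#' @param control A [forest_control()].
#' @return An object of class `lc_forest`.
#' @export
fit_forest <- function(features, control = forest_control()) {
  x <- features$x
  stopifnot(is.matrix(x), nrow(x) == length(features$time),
            nrow(x) == length(features$event))
  if (sum(features$event == 1) == 0)
    stop("cannot fit a survival forest with zero events")
  p <- ncol(x)
  mtry <- if (identical(control$max_features, "sqrt")) ceiling(sqrt(p))
          else ceiling(control$max_features * p)
  mtry <- max(1L, min(p, as.integer(mtry)))
  grid <- sort(unique(features$time[features$event == 1]))
  max_depth <- if (is.infinite(control$max_depth)) .Machine$integer.max
               else as.integer(control$max_depth)
  set.seed(control$seed)
  trees <- .rsf_grow(x, as.numeric(features$time), as.integer(features$event),
                     grid, control$n_trees, mtry, max_depth,
                     control$min_samples_split, control$min_samples_leaf)
  structure(list(trees = trees, grid = grid, control = control,
                 columns = colnames(x), n = nrow(x),
                 n_events = sum(features$event == 1)),
            class = "lc_forest")
}

.forest_newx <- function(forest, rows) {
  x <- if (is.matrix(rows)) rows else rows$x
  stopifnot(is.matrix(x))
  if (!identical(colnames(x), forest$columns))
    stop("prediction rows do not match the training column layout")
  x
}

#' Predict individualized local-control curves
#'
#' Per row, leaf cumulative hazards are averaged across trees on the shared
#' event-time grid and converted to survival by `S(t) = exp(-H(t))`.
#'
#' @param forest An `lc_forest`.
#' @param rows An `lc_features` object or numeric matrix with the training
#'   column layout.
#' @return An [lc_curves] object (one step curve per row).
#' @export
predict_survival <- function(forest, rows) {
  x <- .forest_newx(forest, rows)
  chf <- .rsf_predict_chf(forest$trees, x, length(forest$grid))
  lc_curves(forest$grid, exp(-chf))
}

#' Predict ensemble mortality risk
#'
#' The risk score is the ensemble mortality: the averaged cumulative hazard
#' summed over all grid times. Higher risk means predicted earlier local
#' failure; the score feeds Harrell's concordance index.
#'
#' @inheritParams predict_survival
#' @return A numeric vector, one risk per row.
#' @export
predict_risk <- function(forest, rows) {
  x <- .forest_newx(forest, rows)
  chf <- .rsf_predict_chf(forest$trees, x, length(forest$grid))
  rowSums(chf)
}

#' @export
print.lc_forest <- function(x, ...) {
  cat(sprintf("Random survival forest: %d trees, %d features, %d training rows (%d events)\n",
              x$control$n_trees, length(x$columns), x$n, x$n_events))
  cat(sprintf("Event-time grid: %d points spanning %.2f-%.2f months\n",
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Serialize a fitted forest to JSON for audit and exact re-prediction
#'
#' @param forest An `lc_forest`.
#' @param path Optional output path.
#' @return JSON string (invisibly when `path` is given).
#' @export
forest_to_json <- function(forest, path = NULL) {
  stopifnot(inherits(forest, "lc_forest"))
  ctl <- unclass(forest$control)
  if (is.infinite(ctl$max_depth)) ctl$max_depth <- NULL  # JSON has no Inf
  obj <- list(grid = forest$grid, columns = forest$columns, n = forest$n,
              n_events = forest$n_events, control = ctl,
              trees = lapply(forest$trees, function(tr) {
                tr$leaf_chf <- apply(tr$leaf_chf, 1, identity, simplify = FALSE)
                tr
              }))
  j <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(j, path); return(invisible(j)) }
  j
}

#' Restore a forest serialized with [forest_to_json()]
#'
#' @param json JSON string or path to a JSON file.
#' @return An `lc_forest` predicting identically to the serialized one.
#' @export
forest_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  ctl <- obj$control
  control <- forest_control(n_trees = ctl$n_trees,
                            max_depth = if (is.null(ctl$max_depth)) Inf else ctl$max_depth,
                            min_samples_split = ctl$min_samples_split,
                            min_samples_leaf = ctl$min_samples_leaf,
                            max_features = ctl$max_features, seed = ctl$seed)
  trees <- lapply(obj$trees, function(tr) {
    list(feature = as.integer(unlist(tr$feature)),
         threshold = as.numeric(unlist(tr$threshold)),
         left = as.integer(unlist(tr$left)),
         right = as.integer(unlist(tr$right)),
         leaf_id = as.integer(unlist(tr$leaf_id)),
         leaf_chf = do.call(rbind, lapply(tr$leaf_chf, as.numeric)),
         inbag = as.integer(unlist(tr$inbag)))
  })
  structure(list(trees = trees, grid = as.numeric(unlist(obj$grid)),
                 control = control,
                 columns = as.character(unlist(obj$columns)),
                 n = obj$n, n_events = obj$n_events),
            class = "lc_forest")
}
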