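# Predicted local-control curves (step functions) and clinician-facing
# summaries: local-control probability at fixed horizons and expected
# local-control duration (restricted mean survival time).

#' Collection of local-control step curves
#'
#' @param time Strictly increasing grid of event times (months).
#' @param surv Numeric matrix, one row per case, of survival probabilities at
#'   each grid time; a vector is treated as a single curve. `S(0) = 1`
#'   implicitly; each row must be non-increasing in `[0, 1]`.
#' @return An object of class `lc_curves`.
#' @export
lc_curves <- function(time, surv) {
  if (is.vector(surv)) surv <- matrix(surv, nrow = 1)
  stopifnot(is.numeric(time), ncol(surv) == length(time),
            !is.unsorted(time, strictly = TRUE))
  if (any(surv < -1e-12 | surv > 1 + 1e-12))
    stop("survival probabilities must lie in [0, 1]")
  if (ncol(surv) > 1 && any(surv[, -1, drop = FALSE] -
                              surv[, -ncol(surv), drop = FALSE] > 1e-10))
    stop("survival curves must be non-increasing")
  structure(list(time = as.numeric(time), surv = pmin(pmax(surv, 0), 1)),
            class = "lc_curves")
}

#' @export
length.lc_curves <- function(x) nrow(x$surv)

#' Extract one curve from a collection
#' @param x An `lc_curves` collection.
#' @param i Row index.
#' @param ... Ignored.
#' @export
`[.lc_curves` <- function(x, i, ...) lc_curves(x$time, x$surv[i, , drop = FALSE])

#' @export
print.lc_curves <- function(x, ...) {
  cat(sprintf("%d local-control curve(s) on a %d-point grid (%.2f-%.2f months)\n",
              length(x), length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' @export
plot.lc_curves <- function(x, xlab = "Months since GKRS",
                           ylab = "Local control probability", ...) {
  tt <- c(0, x$time)
  plot(NULL, xlim = range(tt), ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  for (i in seq_len(length(x)))
    lines(stats::stepfun(x$time, c(1, x$surv[i, ])), do.points = FALSE)
  invisible(x)
}

#' Local-control probability at a time point
#'
#' Step-function evaluation of the curve at `t` with the previous-grid-value
#' (right-continuous) convention; `t` before the first grid point gives 1,
#' beyond the last gives the final value.
#'
#' @param curve An `lc_curves` (each row evaluated) .
#' @param t Non-negative time in months.
#' @return Probability vector, one per curve.
#' @export
lc_probability_at <- function(curve, t) {
  stopifnot(inherits(curve, "lc_curves"))
  if (t < 0) stop("t must be non-negative")
  k <- findInterval(t, curve$time)
  if (k == 0) rep(1, length(curve)) else curve$surv[, k]
}

#' Expected local-control duration (restricted mean survival time)
#'
#' Integrates each step curve exactly over `[0, tau]` as a sum of rectangle
#' areas (the curves are genuinely piecewise constant, so no quadrature is
#' involved).
#'
#' @param curve An `lc_curves`.
#' @param tau Horizon in months (> 0).
#' @return Months of expected local control within `[0, tau]`, per curve.
#' @export
expected_lc_duration <- function(curve, tau) {
  stopifnot(inherits(curve, "lc_curves"), tau > 0)
  tt <- curve$time
  keep <- tt < tau
  edges <- c(0, tt[keep], tau)
  widths <- diff(edges)
  vals <- cbind(1, curve$surv[, keep, drop = FALSE])
  as.numeric(vals %*% widths)
}

#' Clinician-facing case summary of a predicted curve
#'
#' @param curve A single-curve `lc_curves`.
#' @param horizons Reporting horizons in months.
#' @param tau Horizon for expected local-control duration.
#' @param dose_gy The prescription dose the curve was predicted under
#'   (annotation only).
#' @return A list of class `case_summary` with `lc_at` (named probabilities),
#'   `expected_lc_months`, `tau` and `dose_gy`.
#' @export
case_summary <- function(curve, horizons = c(6, 12, 18), tau = 18,
                         dose_gy = NA_real_) {
  stopifnot(inherits(curve, "lc_curves"), length(curve) == 1)
  lc <- vapply(horizons, function(h) lc_probability_at(curve, h), 0)
  names(lc) <- paste0("lc_", horizons, "m")
  structure(list(lc_at = lc,
                 expected_lc_months = expected_lc_duration(curve, tau),
                 tau = tau, dose_gy = dose_gy),
            class = "case_summary")
}

#' @export
print.case_summary <- function(x, ...) {
  cat(sprintf("Case summary (dose %.1f Gy):\n", x$dose_gy))
  for (nm in names(x$lc_at))
    cat(sprintf("  local control at %s months: %.3f\n",
                sub("^lc_(\\d+)m$", "\\1", nm), x$lc_at[[nm]]))
  cat(sprintf("  expected local control within %.0f months: %.2f months\n",
              x$tau, x$expected_lc_months))
  invisible(x)
}
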