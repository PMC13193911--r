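# Validation metrics for right-censored predictions: Harrell's C-index,
# Kaplan-Meier censoring distribution, inverse-probability-of-censoring
# weighted (IPCW) Brier score, and its integral over the evaluation horizon.

#' Right-continuous step function
#'
#' Minimal step-function container used for the censoring distribution:
#' value `y0` before the first jump, `y[k]` from jump `x[k]` (inclusive)
#' onward. [eval_step()] evaluates it; `left = TRUE` gives the left limit
#' `f(t-)` via jump bookkeeping (no epsilon arithmetic).
#'
#' @param x Jump times, strictly increasing.
#' @param y Values after each jump.
#' @param y0 Value before the first jump.
#' @return An object of class `lc_stepfun`.
#' @export
lc_stepfun <- function(x, y, y0 = 1) {
  stopifnot(length(x) == length(y), !is.unsorted(x, strictly = TRUE))
  structure(list(x = as.numeric(x), y = as.numeric(y), y0 = y0),
            class = "lc_stepfun")
}

#' Evaluate a step function
#'
#' @param sf An [lc_stepfun()].
#' @param t Evaluation times.
#' @param left If `TRUE`, return the left limit `f(t-)` (jumps at `t`
#'   excluded); otherwise the right-continuous value `f(t)`.
#' @return Numeric vector of values.
#' @export
eval_step <- function(sf, t, left = FALSE) {
  stopifnot(inherits(sf, "lc_stepfun"))
  k <- findInterval(t, sf$x, left.open = left)
  ifelse(k == 0, sf$y0, sf$y[pmax(k, 1)])
}

#' Harrell's concordance index
#'
#' Over comparable pairs (i, j) — `times[i] < times[j]` with `events[i] = 1`
#' — the fraction whose predicted risks are correctly ordered
#' (`risks[i] > risks[j]`), with half credit for tied risks. Pairs with tied
#' times are not comparable (the Harrell convention used throughout this
#' package). Invariant under strictly monotone transforms of the risks.
#'
#' @param times Observed times.
#' @param events Event indicators (1 = failure).
#' @param risks Predicted risk scores (higher = earlier failure).
#' @return Concordance in [0, 1]; errors when no pair is comparable.
#' @export
harrell_cindex <- function(times, events, risks) {
  n <- length(times)
  stopifnot(length(events) == n, length(risks) == n)
  num <- 0; den <- 0
  for (i in which(events == 1)) {
    later <- times > times[i]
    m <- sum(later)
    if (m == 0) next
    den <- den + m
    num <- num + sum(risks[i] > risks[later]) + 0.5 * sum(risks[i] == risks[later])
  }
  if (den == 0) stop("concordance undefined: no comparable pairs")
  num / den
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Product-limit estimate `G(t)` of the censoring survival function,
#' obtained by flipping the event indicator (censorings become the events)
#' and fitting the Kaplan-Meier estimator. Used for IPCW weights; always
#' estimate it on training rows only.
#'
#' @param times Observed times.
#' @param events Event indicators of the failure process (they are flipped
#'   internally).
#' @return An [lc_stepfun()] with `G(0) = 1`.
#' @export
km_censoring <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1)
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  jump <- which(fit$n.event > 0)
  lc_stepfun(fit$time[jump], fit$surv[jump], y0 = 1)
}

#' IPCW Brier score at a single time point
#'
#' Censoring-adjusted squared prediction error at `t`: subjects who failed by
#' `t` contribute `S_i(t)^2 / G(T_i-)`, subjects still under observation
#' beyond `t` contribute `(1 - S_i(t))^2 / G(t)`, and subjects censored
#' before `t` contribute 0; the sum is divided by `n`. With no censoring
#' (`G = 1`) this is the unweighted mean squared error.
#'
#' @param t Evaluation time.
#' @param curves Predicted [lc_curves] (one row per subject).
#' @param times,events Observed outcomes, same order as `curves`.
#' @param G Censoring distribution from [km_censoring()], estimated on
#'   training data.
#' @return Non-negative scalar; errors if a required weight has `G = 0`.
#' @export
brier_score <- function(t, curves, times, events, G) {
  stopifnot(inherits(curves, "lc_curves"), inherits(G, "lc_stepfun"))
  n <- length(times)
  stopifnot(length(events) == n, length(curves) == n)
  s_t <- lc_probability_at(curves, t)
  failed <- times <= t & events == 1
  alive <- times > t
  contrib <- numeric(n)
  if (any(failed)) {
    w <- eval_step(G, times[failed], left = TRUE)
    if (any(w <= 0))
      stop("censoring weight G(t-) is zero at time ",
           min(times[failed][w <= 0]))
    contrib[failed] <- s_t[failed]^2 / w
  }
  if (any(alive)) {
    g_t <- eval_step(G, t)
    if (g_t <= 0)
      stop("censoring weight G(t) is zero at time ", t)
    contrib[alive] <- (1 - s_t[alive])^2 / g_t
  }
  sum(contrib) / n
}

#' Integrated Brier score over the evaluation horizon
#'
#' `(1/tau) * integral of BS(t) dt` on `[0, tau]`, computed by the
#' trapezoidal rule on the grid of unique observed times within the horizon,
#' augmented with 0 and `tau`.
#'
#' @inheritParams brier_score
#' @param tau Evaluation horizon in months (> 0). The package default
#'   elsewhere is 18 months, the largest standard reporting horizon.
#' @return Non-negative scalar.
#' @export
integrated_brier <- function(curves, times, events, G, tau) {
  stopifnot(tau > 0)
  grid <- sort(unique(c(0, times[times <= tau], tau)))
  bs <- vapply(grid, function(t) brier_score(t, curves, times, events, G), 0)
  sum(diff(grid) * (head(bs, -1) + bs[-1]) / 2) / tau
}
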