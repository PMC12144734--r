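# Kaplan-Meier estimation, restricted mean survival time with its
# large-sample variance, and the one-sided DRMST non-inferiority test.

# Aggregate (time, status) into distinct times with event counts and
# at-risk numbers. Ties between events and censorings at the same time are
# events-first (both are still at risk at that time), the product-limit
# convention.
km_aggregate <- function(time, status) {
  o <- order(time)
  t <- time[o]
  e <- as.numeric(status[o])
  n <- length(t)
  new <- !duplicated(t)
  g <- cumsum(new)
  ut <- t[new]
  d <- as.vector(rowsum(e, g))
  m <- tabulate(g)
  nrisk <- n - c(0L, cumsum(m)[-length(m)])
  list(time = ut, n.event = d, n.at = m, n.risk = nrisk, n = n,
       maxtime = t[n], maxtime_event = e[n] > 0)
}

# RMST estimate and variance at tau from raw (time, status); the fast path
# used inside Monte-Carlo loops. Returns c(estimate, variance).
# Variance: sum over event times t_i <= tau of A_i^2 d_i / (n_i (n_i - d_i))
# with A_i the area under the KM curve from t_i to tau; a term with
# n_i = d_i contributes 0. The curve is carried flat beyond the last
# observed time.
rmst_core <- function(time, status, tau) {
  agg <- km_aggregate(time, status)
  idx <- which(agg$n.event > 0 & agg$time <= tau)
  if (!length(idx)) return(c(tau, 0))
  te <- agg$time[idx]
  de <- agg$n.event[idx]
  ne <- agg$n.risk[idx]
  s <- cumprod(1 - de / ne)
  widths <- diff(c(te, tau))
  est <- te[1] + sum(s * widths)           # area: S = 1 before first event
  aw <- s * widths
  A <- rev(cumsum(rev(aw)))
  denom <- ne * (ne - de)
  terms <- ifelse(denom > 0, A^2 * de / denom, 0)
  c(est, sum(terms))
}

#' Kaplan-Meier product-limit fit
#'
#' Minimal product-limit estimator used by the RMST machinery: survival
#' drops only at event times, with ties between events and censorings at
#' equal times resolved events-first.
#'
#' @param time Vector of positive observed times (length at least 2).
#' @param event Logical (or 0/1) event indicators.
#' @return An object of class `"km_curve"`: distinct event times, the
#'   survival value just after each, at-risk and event counts, and the
#'   largest observed time with its censoring status.
#' @export
km_fit <- function(time, event) {
  if (length(time) < 2 || length(time) != length(event))
    stopf("'time' and 'event' must have equal length >= 2")
  if (any(!is.finite(time)) || any(time <= 0))
    stopf("'time' must be positive and finite")
  agg <- km_aggregate(time, event)
  idx <- which(agg$n.event > 0)
  structure(list(time = agg$time[idx],
                 surv = cumprod(1 - agg$n.event[idx] / agg$n.risk[idx]),
                 n.risk = agg$n.risk[idx], n.event = agg$n.event[idx],
                 n = agg$n, maxtime = agg$maxtime,
                 maxtime_event = agg$maxtime_event),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times, last observation %.4g (%s)\n",
              x$n, length(x$time), x$maxtime,
              if (x$maxtime_event) "event" else "censored"))
  invisible(x)
}

#' Restricted mean survival time from censored data
#'
#' Area under the Kaplan-Meier curve up to `tau`, with the standard
#' large-sample variance
#' \deqn{\widehat{Var} = \sum_{t_i \le \tau} A_i^2
#'   \frac{d_i}{n_i(n_i - d_i)}, \qquad
#'   A_i = \int_{t_i}^{\tau} \hat S(u)\,du.}
#' If the last observed time precedes `tau` the curve is carried flat to
#' `tau` (with a warning), which mirrors how sparse late follow-up
#' degrades RMST estimation rather than failing outright.
#'
#' @param time Vector of positive observed times.
#' @param event Event indicators.
#' @param tau Positive restriction time.
#' @return An object of class `"rmst_estimate"`: `estimate`, `variance`,
#'   `tau`, `n` and `n_events` (events by `tau`).
#' @examples
#' rmst_km(c(1, 2, 3), c(1, 1, 1), tau = 3)   # estimate 2, the mean of min(T, 3)
#' @export
rmst_km <- function(time, event, tau) {
  check_scalar(tau, "tau", positive = TRUE)
  if (length(time) < 2 || length(time) != length(event))
    stopf("'time' and 'event' must have equal length >= 2")
  if (any(!is.finite(time)) || any(time <= 0))
    stopf("'time' must be positive and finite")
  if (max(time) < tau)
    warnf("last observed time %.4g precedes tau = %.4g; KM curve carried flat",
          max(time), tau)
  core <- rmst_core(time, event, tau)
  structure(list(estimate = core[1], variance = core[2], tau = tau,
                 n = length(time), n_events = sum(event[time <= tau] > 0)),
            class = "rmst_estimate")
}

#' @export
print.rmst_estimate <- function(x, ...) {
  cat(sprintf("RMST at tau = %g: %.4f (SE %.4f), n = %d, %d events by tau\n",
              x$tau, x$estimate, sqrt(x$variance), x$n, x$n_events))
  invisible(x)
}

#' One-sided DRMST non-inferiority test
#'
#' Tests \eqn{H_0: R_2(\tau) - R_1(\tau) \le -\delta} against
#' \eqn{H_1: \Delta(\tau) > -\delta}: non-inferiority is claimed when
#' \eqn{\hat\Delta(\tau) - z_{1-\alpha}\,SE(\hat\Delta(\tau)) > -\delta}.
#' Accepts per-subject data, e.g. a [simulate_trial()] data frame or a
#' table read with [read_trial()]; the first level of `arm` is the active
#' control.
#'
#' @param time Observed times, or a data frame with columns `time`,
#'   `event`, `arm`.
#' @param event Event indicators (ignored when `time` is a data frame).
#' @param arm Two-level factor; first level = active control.
#' @param tau RMST horizon.
#' @param margin Positive non-inferiority margin on the DRMST scale
#'   (\eqn{\delta}, or the adjusted \eqn{\delta^*} under switching).
#' @param alpha One-sided significance level.
#' @return An object of class `"drmst_test"` with the DRMST estimate, its
#'   standard error, the one-sided lower confidence bound, the margin and
#'   the rejection flag.
#' @export
drmst_test <- function(time, event = NULL, arm = NULL, tau, margin,
                       alpha = 0.025) {
  if (is.data.frame(time)) {
    dat <- time
    if (!all(c("time", "event", "arm") %in% names(dat)))
      stopf("data frame input needs columns 'time', 'event', 'arm'")
    event <- dat$event
    arm <- dat$arm
    time <- dat$time
  }
  check_scalar(tau, "tau", positive = TRUE)
  check_scalar(margin, "margin", positive = TRUE)
  check_prob(alpha, "alpha", open_left = TRUE, open_right = TRUE)
  arm <- as.factor(arm)
  if (nlevels(arm) != 2) stopf("'arm' must have exactly two levels")
  ctrl <- arm == levels(arm)[1]
  r1 <- rmst_core(time[ctrl], event[ctrl], tau)
  r2 <- rmst_core(time[!ctrl], event[!ctrl], tau)
  est <- r2[1] - r1[1]
  se <- sqrt(r1[2] + r2[2])
  lower <- est - stats::qnorm(1 - alpha) * se
  structure(list(estimate = est, se = se, lower = lower, margin = margin,
                 alpha = alpha, reject = lower > -margin,
                 rmst_control = r1[1], rmst_experimental = r2[1],
                 tau = tau, arms = levels(arm)),
            class = "drmst_test")
}

#' @export
print.drmst_test <- function(x, ...) {
  cat("One-sided non-inferiority test on the RMST difference\n")
  cat(sprintf("  RMST at tau = %g: %s %.4f, %s %.4f\n", x$tau,
              x$arms[1], x$rmst_control, x$arms[2], x$rmst_experimental))
  cat(sprintf("  DRMST = %.4f (SE %.4f), one-sided %g%% lower bound %.4f\n",
              x$estimate, x$se, 100 * (1 - x$alpha), x$lower))
  cat(sprintf("  margin -delta = %.4f: %s\n", -x$margin,
              if (x$reject) "non-inferiority claimed (H0 rejected)"
              else "non-inferiority NOT shown"))
  invisible(x)
}
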