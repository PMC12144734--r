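# Accrual (staggered entry) and censoring models.
#
# Entry times follow a linear density f_V(v) = a* + b* v on [0, Ta]:
# decreasing (a* = 2/Ta, b* = -2/Ta^2), uniform (a* = 1/Ta, b* = 0) or
# increasing (a* = 0, b* = 2/Ta^2). Censoring given entry v mixes a dropout
# law d(c) on (0, Te - v) with an atom of mass Dbar(Te - v) at the
# administrative horizon c = Te - v.

#' Accrual entry specification
#'
#' @param pattern One of `"unif"` (alias `"uniform"`), `"decreasing"`,
#'   `"increasing"`: the linear entry density over the accrual window.
#' @param Ta Nonnegative accrual duration. `Ta = 0` means all participants
#'   enter at the trial start, regardless of `pattern`.
#' @return An object of class `"entry_spec"`.
#' @export
entry_spec <- function(pattern = c("unif", "uniform", "decreasing", "increasing"),
                       Ta) {
  pattern <- match.arg(pattern)
  if (pattern == "uniform") pattern <- "unif"
  check_scalar(Ta, "Ta", nonneg = TRUE)
  structure(list(pattern = pattern, Ta = Ta), class = "entry_spec")
}

# Linear density f_V(v) on [0, Ta]; only valid when Ta > 0.
entry_density <- function(v, entry) {
  Ta <- entry$Ta
  co <- switch(entry$pattern,
               decreasing = c(2 / Ta, -2 / Ta^2),
               unif       = c(1 / Ta, 0),
               increasing = c(0, 2 / Ta^2))
  ifelse(v >= 0 & v <= Ta, co[1] + co[2] * v, 0)
}

# CDF of the entry time (used by property tests).
entry_cdf <- function(v, entry) {
  Ta <- entry$Ta
  if (Ta == 0) return(as.numeric(v >= 0))
  v <- pmin(pmax(v, 0), Ta)
  switch(entry$pattern,
         decreasing = 2 * v / Ta - (v / Ta)^2,
         unif       = v / Ta,
         increasing = (v / Ta)^2)
}

#' Sample entry times
#'
#' Inverse-CDF draws: decreasing \eqn{V = T_a(1 - \sqrt{1-U})}, uniform
#' \eqn{V = T_a U}, increasing \eqn{V = T_a\sqrt{U}}. With `Ta = 0` all
#' entries are exactly zero.
#'
#' @param n Number of draws.
#' @param entry An [entry_spec()] object.
#' @export
sample_entry <- function(n, entry) {
  stopifnot(inherits(entry, "entry_spec"))
  if (entry$Ta == 0) return(numeric(n))
  u <- stats::runif(n)
  entry$Ta * switch(entry$pattern,
                    decreasing = 1 - sqrt(1 - u),
                    unif       = u,
                    increasing = sqrt(u))
}

#' Dropout-censoring specification
#'
#' @param family `"none"` (administrative censoring only), `"unif"`
#'   (dropout uniform on `(0, param)`) or `"exp"` (dropout exponential with
#'   rate `param`).
#' @param param Dropout parameter; required unless `family = "none"`.
#' @param Te Positive trial duration (administrative horizon).
#' @return An object of class `"dropout_spec"`.
#' @export
dropout_spec <- function(family = c("none", "unif", "exp"), param = NULL, Te) {
  family <- match.arg(family)
  check_scalar(Te, "Te", positive = TRUE)
  if (family == "none") {
    param <- NULL
  } else {
    check_scalar(param, "param", positive = TRUE)
  }
  structure(list(family = family, param = param, Te = Te),
            class = "dropout_spec")
}

#' Administrative censoring probability
#'
#' Probability that a participant is still event-free at the trial end,
#' \eqn{\int f_V(v)\,S(T_e - v)\,dv}, i.e. the censoring probability when
#' there is no dropout. This is the floor below which a target total
#' censoring probability is infeasible.
#'
#' @param event A [gg_spec()] event-time law.
#' @param entry An [entry_spec()] accrual law.
#' @param Te Trial duration; must be at least the accrual duration.
#' @export
admin_censor_prob <- function(event, entry, Te) {
  stopifnot(inherits(event, "gg_spec"), inherits(entry, "entry_spec"))
  check_scalar(Te, "Te", positive = TRUE)
  if (Te < entry$Ta)
    stopf("trial duration Te = %g is shorter than accrual duration Ta = %g",
          Te, entry$Ta)
  if (entry$Ta == 0) return(gg_survival(Te, event))
  stats::integrate(function(v) entry_density(v, entry) *
                     gg_survival(Te - v, event),
                   0, entry$Ta, abs.tol = 1e-10, rel.tol = 1e-10,
                   subdivisions = 500L)$value
}

# P(censored before event | entry v) for one dropout law:
# integral of the dropout density against S_T on (0, Te - v) plus the
# administrative atom Dbar(Te - v) * S_T(Te - v).
censor_prob_given_entry <- function(v, dropout, event) {
  Te <- dropout$Te
  h <- Te - v
  S_adm <- gg_survival(h, event)
  switch(dropout$family,
         none = S_adm,
         unif = {
           p <- dropout$param
           up <- min(p, h)
           inner <- stats::integrate(function(u) gg_survival(u, event),
                                     0, up, abs.tol = 1e-10,
                                     rel.tol = 1e-10)$value / p
           inner + max(0, 1 - h / p) * S_adm
         },
         exp = {
           # substitute w = exp(-lam u): keeps the integrand bounded even
           # when the dropout density is a sharp spike at 0 (large rates)
           lam <- dropout$param
           wlo <- exp(-lam * h)
           inner <- if (wlo >= 1) 0
           else stats::integrate(function(w) gg_survival(-log(w) / lam, event),
                                 wlo, 1, abs.tol = 1e-10,
                                 rel.tol = 1e-10)$value
           inner + wlo * S_adm
         })
}

#' Total censoring probability of one arm under no switching
#'
#' Nested quadrature of the censoring mixture over the entry distribution:
#' the probability that the censoring time \eqn{C = \min(D, T_e - V)}
#' precedes the event time.
#'
#' @param dropout A [dropout_spec()] object.
#' @param event A [gg_spec()] event-time law for the arm.
#' @param entry An [entry_spec()] accrual law.
#' @export
total_censor_prob <- function(dropout, event, entry) {
  stopifnot(inherits(dropout, "dropout_spec"), inherits(event, "gg_spec"),
            inherits(entry, "entry_spec"))
  if (entry$Ta == 0)
    return(censor_prob_given_entry(0, dropout, event))
  f <- Vectorize(function(v) entry_density(v, entry) *
                   censor_prob_given_entry(v, dropout, event))
  stats::integrate(f, 0, entry$Ta, abs.tol = 1e-9, rel.tol = 1e-9,
                   subdivisions = 200L)$value
}

#' Calibrate the dropout parameter from a target censoring probability
#'
#' Solves, by monotone root-finding on the probability scale, for the
#' dropout parameter such that the total censoring probability of the
#' active-control arm under no switching equals `target`. The target must
#' be at least the administrative censoring probability (the no-dropout
#' floor); a target equal to the floor returns a no-dropout specification.
#'
#' @param target Target total censoring probability in `[admin, 1)`.
#' @param event Active-control [gg_spec()] event-time law.
#' @param entry An [entry_spec()] accrual law.
#' @param Te Trial duration.
#' @param family Dropout family, `"unif"` or `"exp"`.
#' @return A [dropout_spec()] whose total censoring probability matches
#'   `target` to within 1e-8.
#' @export
solve_dropout_param <- function(target, event, entry, Te,
                                family = c("unif", "exp")) {
  family <- match.arg(family)
  check_prob(target, "target", open_right = TRUE)
  p_adm <- admin_censor_prob(event, entry, Te)
  if (target < p_adm - 1e-9)
    stopf(paste0("target censoring probability %.6g is below the ",
                 "administrative-only censoring probability %.6g; ",
                 "it cannot be reached by adding dropout"), target, p_adm)
  if (target <= p_adm + 1e-8) {
    warnf("target %.6g equals the administrative censoring probability %.6g; no dropout needed",
          target, p_adm)
    return(dropout_spec("none", Te = Te))
  }
  f <- function(lp) {
    d <- dropout_spec(family, exp(lp), Te)
    total_censor_prob(d, event, entry) - target
  }
  # unif: prob decreases from 1 (param -> 0) to p_adm (param -> Inf);
  # exp: prob increases from p_adm (rate -> 0) to 1 (rate -> Inf).
  lo <- log(Te) - 20
  hi <- log(Te) + 20
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12, maxiter = 200L)
  sol <- dropout_spec(family, exp(root$root), Te)
  achieved <- total_censor_prob(sol, event, entry)
  if (abs(achieved - target) > 1e-8)
    stopf("dropout calibration did not converge: achieved %.8f vs target %.8f",
          achieved, target)
  sol
}

#' Sample censoring times
#'
#' Draws a dropout time from the dropout law (infinite when
#' `family = "none"`) and truncates it at the administrative horizon
#' `Te - entry_time`; the atom at the horizon has mass
#' \eqn{\bar D(T_e - v)}.
#'
#' @param dropout A [dropout_spec()] object.
#' @param entry_time Vector of entry times, all at most `Te`.
#' @return Censoring times, one per entry time.
#' @export
sample_censoring <- function(dropout, entry_time) {
  stopifnot(inherits(dropout, "dropout_spec"))
  if (any(entry_time > dropout$Te))
    stopf("entry times must not exceed the trial duration Te = %g", dropout$Te)
  horizon <- dropout$Te - entry_time
  n <- length(entry_time)
  switch(dropout$family,
         none = horizon,
         unif = pmin(stats::runif(n, 0, dropout$param), horizon),
         exp  = pmin(stats::rexp(n, dropout$param), horizon))
}
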