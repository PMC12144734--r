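# Treatment-switching model: switch-time distributions moment-matched to
# (rs, rhos), switch eligibility, and the rank-preserving structural
# failure time (RPSFT) counterfactual for switchers.
#
# Correlated options write the switch time as S = X T1 with X independent
# of the event time T1: "unif" (X ~ U(0,1), forces rs = 1/2), "beta" and
# "gamma" with X-law parameters solved from rs = E(S)/E(T1) and
# rhos = corr(S, T1). "indepExp" draws S exponential with rate
# 1/(rs E(T1)); a numeric option fixes S at a given time.

#' Treatment-switching specification
#'
#' @param s.dist Switch-time distribution: `"unif"`, `"beta"`, `"gamma"`,
#'   `"indepExp"`, or a single nonnegative number giving a fixed switch
#'   time (0 = switching at the trial start).
#' @param ps Switching probability among participants who qualify
#'   (whose switch time precedes their latent event time).
#' @param rs Ratio of the mean switch time to the mean event time of the
#'   switching arm, \eqn{r_s = E(S)/E(T_1)}.
#' @param rhos Correlation between the switch time and the event time, in
#'   (0, 1); ignored by `"unif"` (whose correlation is structural),
#'   `"indepExp"` and fixed times.
#' @param TXswitch Switching direction: `"1to2"` (control participants
#'   adopt the experimental regimen) or `"2to1"`.
#' @param af Positive multiplier for the RPSFT acceleration factor, for
#'   sensitivity analyses around the common-treatment-effect assumption.
#' @return An object of class `"switch_spec"`.
#' @export
switch_spec <- function(s.dist = "gamma", ps = 0.2, rs = 0.5, rhos = 0.775,
                        TXswitch = c("1to2", "2to1"), af = 1) {
  TXswitch <- match.arg(TXswitch)
  check_prob(ps, "ps")
  check_scalar(af, "af", positive = TRUE)
  fixed_time <- NULL
  if (is.numeric(s.dist)) {
    check_scalar(s.dist, "s.dist", nonneg = TRUE)
    fixed_time <- s.dist
    s.dist <- "fixed"
  } else {
    s.dist <- match.arg(s.dist, c("unif", "beta", "gamma", "indepExp"))
    check_scalar(rs, "rs", positive = TRUE)
    if (s.dist %in% c("beta", "gamma"))
      check_prob(rhos, "rhos", open_left = TRUE, open_right = TRUE)
    if (s.dist == "unif" && abs(rs - 0.5) > 1e-12)
      stopf(paste0("s.dist = \"unif\" forces rs = E(S)/E(T1) = 0.5 ",
                   "(X ~ U(0,1)); rs = %g is not attainable"), rs)
    if (s.dist %in% c("unif", "beta") && rs >= 1)
      stopf("s.dist = \"%s\" requires rs < 1 (S < T1 always)", s.dist)
  }
  structure(list(dist = s.dist, ps = ps, rs = rs, rhos = rhos,
                 fixed_time = fixed_time, TXswitch = TXswitch, af = af),
            class = "switch_spec")
}

# Table-style rhos expression for solved parameters, used to verify the
# closed-form inversion: corr(XT, T) with Var(X) = vx, E(X) = rs.
switch_rho_implied <- function(rs, vx, ET, ET2) {
  VT <- ET2 - ET^2
  rs * sqrt(VT) / sqrt(rs^2 * VT + vx * ET2)
}

#' Solve switch-time distribution parameters from (rs, rhos)
#'
#' Moment-matches the switch-time law to the switching arm's event-time
#' law. For `"beta"` and `"gamma"` the target correlation fixes
#' \eqn{Var(X) = r_s^2 Var(T_1)(1/\rho_s^2 - 1)/E(T_1^2)}; the beta option
#' then needs \eqn{Var(X) < r_s(1 - r_s)}, otherwise the requested
#' correlation is infeasible and the attainable range is reported. The
#' solved parameters reproduce (rs, rhos) to 1e-8.
#'
#' @param spec A [switch_spec()] object.
#' @param control The event-time [gg_spec()] law of the switching arm.
#' @return An object of class `"solved_switch"`: the spec plus solved
#'   parameters (`shape1`/`shape2` for beta, `shape`/`rate` for gamma,
#'   `rate` for indepExp) and the implied correlation.
#' @export
solve_switch_params <- function(spec, control) {
  stopifnot(inherits(spec, "switch_spec"), inherits(control, "gg_spec"))
  ET <- gg_moment(control, 1)
  ET2 <- gg_moment(control, 2)
  VT <- ET2 - ET^2
  rs <- spec$rs
  params <- list()
  rho_implied <- NA_real_
  if (spec$dist == "unif") {
    # X ~ U(0,1): E(X) = 1/2, Var(X) = 1/12; the correlation is structural.
    rho_implied <- switch_rho_implied(0.5, 1 / 12, ET, ET2)
  } else if (spec$dist %in% c("beta", "gamma")) {
    vx <- rs^2 * VT * (1 / spec$rhos^2 - 1) / ET2
    if (spec$dist == "beta") {
      if (vx >= rs * (1 - rs)) {
        rho_min <- switch_rho_implied(rs, rs * (1 - rs), ET, ET2)
        stopf(paste0("rhos = %.4g is not attainable by the beta option at ",
                     "rs = %.4g for this event-time law; attainable range ",
                     "is (%.4g, 1)"), spec$rhos, rs, rho_min)
      }
      ab <- rs * (1 - rs) / vx - 1
      params <- list(shape1 = rs * ab, shape2 = (1 - rs) * ab)
      rho_implied <- switch_rho_implied(rs, vx, ET, ET2)
    } else {
      rate <- rs / vx
      params <- list(shape = rs * rate, rate = rate)
      rho_implied <- switch_rho_implied(rs, vx, ET, ET2)
    }
    if (abs(rho_implied - spec$rhos) > 1e-8)
      stopf("internal error: solved switch parameters give rhos = %.10g, target %.10g",
            rho_implied, spec$rhos)
  } else if (spec$dist == "indepExp") {
    params <- list(rate = 1 / (rs * ET))
  }
  structure(c(unclass(spec),
              list(params = params, rho_implied = rho_implied,
                   ET1 = ET, ET1sq = ET2)),
            class = "solved_switch")
}

#' Sample switch times and eligibility
#'
#' For the correlated options draws \eqn{S_i = X_i T_{1,i}} with
#' \eqn{X_i} i.i.d. from the solved law; `"indepExp"` draws S
#' independently of the event times; a fixed option returns the constant.
#' A participant qualifies for switching only when the switch time
#' precedes the latent event time (`S < T1`), the domain on which the
#' RPSFT transform is defined.
#'
#' @param solved A [solve_switch_params()] result.
#' @param t1_latent Vector of positive latent event times.
#' @return A list with `switch_time` and logical `eligible`.
#' @export
sample_switch_times <- function(solved, t1_latent) {
  stopifnot(inherits(solved, "solved_switch"))
  n <- length(t1_latent)
  s <- switch(solved$dist,
              unif     = stats::runif(n) * t1_latent,
              beta     = stats::rbeta(n, solved$params$shape1,
                                      solved$params$shape2) * t1_latent,
              gamma    = stats::rgamma(n, solved$params$shape,
                                       rate = solved$params$rate) * t1_latent,
              indepExp = stats::rexp(n, solved$params$rate),
              fixed    = rep(solved$fixed_time, n))
  list(switch_time = s, eligible = s < t1_latent)
}

#' RPSFT counterfactual event time for a switcher
#'
#' A participant switching at time `s` keeps the elapsed time and has the
#' remaining latent time stretched by the acceleration factor:
#' \eqn{T^* = s + (T_1 - s)\,\mathrm{accel}}, with
#' \eqn{\mathrm{accel} = af \cdot m_2/m_1} for control-to-experimental
#' switching (reciprocal for the reverse direction). `accel = 1` is the
#' identity.
#'
#' @param t1 Vector of latent event times.
#' @param s Switch times, each strictly before the corresponding `t1`.
#' @param accel Positive acceleration factor.
#' @export
apply_switch <- function(t1, s, accel) {
  check_scalar(accel, "accel", positive = TRUE)
  if (any(s >= t1))
    stopf("switch times must precede the latent event times (eligibility S < T1)")
  s + (t1 - s) * accel
}
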