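# Monte-Carlo power calculation with the switching-adjusted margin.
#
# Under switching the intention-to-treat control arm is a mixture of pure
# and counterfactually accelerated subjects, with RMST R1*(tau). Testing
# with the unadjusted margin delta then inflates (or deflates) the type-I
# error; the adjusted margin
#     delta* = R1*(tau) - R1(tau) + delta
# restores equivalence with the no-switching test, since
# R1*(tau) - delta* = R1(tau) - delta. For the reverse direction (2to1)
# the mixed arm enters the difference with a positive sign and
# delta* = delta + R2(tau) - R2*(tau).

# Which arm switches, its size, pure law, entry and dropout pieces.
switch_arm_info <- function(design, solved) {
  to2 <- design$TXswitch == "1to2"
  list(to2 = to2,
       nn = if (to2) solved$n1 else solved$n2,
       spec = solved$switch_arm_spec,
       R_pure = true_rmst(solved$switch_arm_spec, design$tau))
}

#' Estimate the switching-adjusted non-inferiority margin
#'
#' Simulates the mixed switching arm `n_simulations` times, averages the
#' Kaplan-Meier RMST estimates at `tau` to obtain the mixed-arm RMST, and
#' shifts the unadjusted margin by the switching-induced change. The pure
#' RMST is the analytic restricted mean of the arm's parametric law; the
#' mixed RMST is a simulation average, so the adjustment mixes analytic
#' and Monte-Carlo quantities. When `ps = 0` or the acceleration factor
#' is 1 switching cannot move the RMST and the margin is returned
#' unchanged without simulation.
#'
#' @param design An [ni_design()] object with `n` set.
#' @return A list with `delta`, `delta_star`, `R_pure`, `R_mixed` (`NA`
#'   when no simulation is needed) and `mc_se` (Monte-Carlo standard
#'   error of `R_mixed`).
#' @export
estimate_adjusted_margin <- function(design) {
  stopifnot(inherits(design, "ni_design"))
  if (is.null(design$n)) stopf("'n' must be set")
  solved <- solve_design(design)
  streams <- make_streams(design$seed, design$n_simulations)
  old_rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old_rng), add = TRUE)
  adjusted_margin(design, solved, streams)
}

# Internal worker; assumes RNG state is managed by the caller and that
# `streams` holds at least n_simulations substreams for the mixed-arm
# simulations.
adjusted_margin <- function(design, solved, streams) {
  delta <- solved$delta
  info <- switch_arm_info(design, solved)
  if (design$ps == 0 || solved$accel == 1)
    return(list(delta = delta, delta_star = delta, R_pure = info$R_pure,
                R_mixed = NA_real_, mc_se = NA_real_))
  nsim <- design$n_simulations
  rhat <- numeric(nsim)
  for (l in seq_len(nsim)) {
    use_stream(streams[[l]])
    a <- sim_arm(info$nn, info$spec, solved$entry, solved$dropout,
                 solved$switch, solved$accel)
    rhat[l] <- rmst_core(a$time, a$event, design$tau)[1]
  }
  R_mixed <- mean(rhat)
  delta_star <- if (info$to2) R_mixed - info$R_pure + delta
  else delta + info$R_pure - R_mixed
  if (delta_star <= 0)
    stopf(paste0("adjusted margin is not positive (delta* = %.6g): the ",
                 "switching-induced RMST shift exceeds the margin delta = ",
                 "%.6g; the design is infeasible"), delta_star, delta)
  list(delta = delta, delta_star = delta_star, R_pure = info$R_pure,
       R_mixed = R_mixed, mc_se = stats::sd(rhat) / sqrt(nsim))
}

#' Monte-Carlo power of the DRMST non-inferiority test
#'
#' Solves all design calibrations once (event-time scales, margin,
#' dropout parameter, switch-time parameters), estimates the adjusted
#' margin, then simulates `n_simulations` complete trials and reports the
#' fraction rejecting the one-sided non-inferiority null, together with
#' the expected numbers of observed events per arm. Fully reproducible:
#' the master seed spawns one RNG substream per simulation (margin
#' estimation and power evaluation use disjoint substream blocks).
#'
#' @param design An [ni_design()] object; alternatively pass the design
#'   parameters directly through `...` (they are forwarded to
#'   [ni_design()]).
#' @param ... Design parameters when `design` is not supplied.
#' @param adjusted Use the switching-adjusted margin \eqn{\delta^*}
#'   (default). `FALSE` tests with the unadjusted \eqn{\delta}, which is
#'   how the type-I error inflation under switching is quantified.
#' @return An object of class `"ni_power"`: `power`, `E1`, `E2`, `delta`,
#'   `delta_star`, `R1`, `R2`, `R_mixed`, Monte-Carlo standard errors and
#'   the design used.
#' @examples
#' \donttest{
#' p <- calculate_power(n = 232, m1 = 6.0, m2 = 6.4, f1 = 0.8, ps = 0,
#'                      Ta = 0, Te = 26, tau = 12, censoring.prob = 0.05,
#'                      one.sided.alpha = 0.005, n_simulations = 500)
#' p
#' }
#' @export
calculate_power <- function(design = NULL, ..., adjusted = TRUE) {
  if (is.null(design)) design <- ni_design(...)
  stopifnot(inherits(design, "ni_design"))
  if (is.null(design$n)) stopf("'n' must be set for a power calculation")
  solved <- solve_design(design)
  power_run(design, solved, adjusted)
}

# Core Monte-Carlo loop shared by calculate_power and calculate_size.
power_run <- function(design, solved, adjusted = TRUE) {
  nsim <- design$n_simulations
  old_rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old_rng), add = TRUE)
  streams <- make_streams(design$seed, 2L * nsim)
  adj <- adjusted_margin(design, solved, streams)
  margin_use <- if (adjusted) adj$delta_star else adj$delta
  z <- stats::qnorm(1 - design$one.sided.alpha)
  tau <- design$tau
  to2 <- design$TXswitch == "1to2"
  rejections <- logical(nsim)
  ev1 <- numeric(nsim)
  ev2 <- numeric(nsim)
  for (l in seq_len(nsim)) {
    use_stream(streams[[nsim + l]])
    a1 <- sim_arm(solved$n1, solved$spec1, solved$entry, solved$dropout,
                  if (to2) solved$switch else NULL, solved$accel)
    a2 <- sim_arm(solved$n2, solved$spec2, solved$entry, solved$dropout,
                  if (!to2) solved$switch else NULL, solved$accel)
    r1 <- rmst_core(a1$time, a1$event, tau)
    r2 <- rmst_core(a2$time, a2$event, tau)
    rejections[l] <- (r2[1] - r1[1]) - z * sqrt(r1[2] + r2[2]) > -margin_use
    ev1[l] <- sum(a1$event)
    ev2[l] <- sum(a2$event)
  }
  pw <- mean(rejections)
  structure(list(power = pw,
                 mc_se = sqrt(pw * (1 - pw) / nsim),
                 E1 = mean(ev1), E2 = mean(ev2),
                 delta = adj$delta, delta_star = adj$delta_star,
                 R1 = solved$R1, R2 = solved$R2,
                 R_pure = adj$R_pure, R_mixed = adj$R_mixed,
                 margin_mode = solved$margin$mode,
                 margin_used = margin_use, adjusted = adjusted,
                 n = solved$n1, n2 = solved$n2, r = design$r,
                 n_simulations = nsim, seed = design$seed,
                 alpha = design$one.sided.alpha,
                 dropout = solved$dropout, switch = solved$switch,
                 design = design),
            class = "ni_power")
}

#' @export
print.ni_power <- function(x, ...) {
  cat("Monte-Carlo power, DRMST non-inferiority test (ITT)\n")
  cat(sprintf("  n = %d control + %d experimental; %d simulations (seed %d)\n",
              x$n, x$n2, x$n_simulations, x$seed))
  cat(sprintf("  margin delta = %.4f (%s)", x$delta, x$margin_mode))
  if (!is.na(x$R_mixed))
    cat(sprintf("; adjusted delta* = %.4f", x$delta_star))
  cat(sprintf("; test used %s margin %.4f\n",
              if (x$adjusted) "adjusted" else "unadjusted", x$margin_used))
  cat(sprintf("  power = %.3f (MC SE %.4f) at one-sided alpha = %g\n",
              x$power, x$mc_se, x$alpha))
  cat(sprintf("  expected events: E1 = %.1f, E2 = %.1f\n", x$E1, x$E2))
  invisible(x)
}

#' @export
summary.ni_power <- function(object, ...) {
  out <- object[c("power", "mc_se", "E1", "E2", "delta", "delta_star",
                  "R1", "R2", "R_mixed", "n", "n2", "r", "n_simulations",
                  "seed", "alpha", "adjusted")]
  class(out) <- "summary.ni_power"
  out
}

#' @export
print.summary.ni_power <- function(x, ...) {
  cat(sprintf(paste0("power %.3f (SE %.4f); delta %.4f -> delta* %.4f; ",
                     "R1 %.4f, R2 %.4f; E1 %.1f, E2 %.1f; n %d + %d\n"),
              x$power, x$mc_se, x$delta, x$delta_star, x$R1, x$R2,
              x$E1, x$E2, x$n, x$n2))
  invisible(x)
}

#' @export
coef.ni_power <- function(object, ...) {
  c(power = object$power, delta = object$delta,
    delta_star = object$delta_star, E1 = object$E1, E2 = object$E2)
}
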