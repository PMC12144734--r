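#' Specify a non-inferiority trial design
#'
#' Collects the full design surface of the simulation-based power and
#' sample-size calculator: arm sizes, event-time laws, margin option,
#' switching model, accrual pattern, censoring target and analysis
#' settings. Arguments keep the field's conventional names (`s.dist`,
#' `censoring.prob`, `lossfu.dist`, `one.sided.alpha`, ...).
#'
#' @param n Active-control arm size (integer, at least 2). May be omitted
#'   when the design is used for a sample-size search.
#' @param r Allocation ratio: experimental-arm size is `round(r * n)`
#'   (half away from zero). Default 1.
#' @param m1,m2 Median survival of the active-control and experimental
#'   arms, in time units.
#' @param shape,k Generalized-gamma shape parameters, shared by both arms
#'   (and the hypothetical placebo). Defaults 1 and 1 (exponential).
#' @param f1 Preserved fraction of the control RMST (margin option 1).
#' @param m0,f2 Hypothetical-placebo median survival and preserved
#'   fraction of the control-vs-placebo DRMST (margin option 2).
#' @param margin Explicit numeric DRMST margin (> 0), e.g. one converted
#'   from a hazard-ratio margin via [margin_from_hr()]. Overrides the
#'   other options.
#' @param ps Switching probability among qualifying participants.
#'   Default 0.2.
#' @param rs Ratio of mean switch time to mean event time. Default 0.5.
#' @param rhos Correlation between switch time and event time.
#'   Default 0.775.
#' @param s.dist Switch-time distribution (`"unif"`, `"beta"`, `"gamma"`,
#'   `"indepExp"`, or a fixed numeric time). Default `"gamma"`.
#' @param entry Entry pattern: `"unif"`, `"decreasing"` or `"increasing"`.
#'   Default `"unif"`.
#' @param censoring.prob `"AC.only"` (administrative censoring only) or
#'   the total censoring probability of the control arm under no
#'   switching, used to calibrate the dropout law. Default `"AC.only"`.
#' @param lossfu.dist Dropout-censoring family, `"unif"` or `"exp"`.
#'   Default `"unif"`.
#' @param Ta,Te Accrual duration and trial duration (0 <= Ta <= Te).
#' @param tau RMST horizon; defaults to `Te` and must not exceed it.
#' @param one.sided.alpha One-sided significance level. Default 0.025.
#' @param TXswitch Switching direction, `"1to2"` or `"2to1"`.
#'   Default `"1to2"`.
#' @param af Multiplier for the RPSFT acceleration factor. Default 1.
#' @param n_simulations Number of Monte-Carlo trials. Default 5000.
#' @param seed Master simulation seed. Default 2024.
#' @return An object of class `"ni_design"`.
#' @examples
#' d <- ni_design(n = 232, m1 = 6.0, m2 = 6.4, f1 = 0.8, ps = 0,
#'                Ta = 0, Te = 26, tau = 12, censoring.prob = 0.05,
#'                one.sided.alpha = 0.005)
#' d
#' @export
ni_design <- function(n = NULL, r = 1, m1, m2, shape = 1, k = 1,
                      f1 = NULL, m0 = NULL, f2 = NULL, margin = NULL,
                      ps = 0.2, rs = 0.5, rhos = 0.775, s.dist = "gamma",
                      entry = "unif", censoring.prob = "AC.only",
                      lossfu.dist = "unif", Ta, Te, tau = Te,
                      one.sided.alpha = 0.025, TXswitch = "1to2", af = 1,
                      n_simulations = 5000, seed = 2024) {
  if (!is.null(n)) {
    check_scalar(n, "n", positive = TRUE, integer = TRUE)
    if (n < 2) stopf("'n' must be at least 2")
  }
  check_scalar(r, "r", nonneg = TRUE)
  check_scalar(m1, "m1", positive = TRUE)
  check_scalar(m2, "m2", positive = TRUE)
  check_scalar(shape, "shape", positive = TRUE)
  check_scalar(k, "k", positive = TRUE)
  check_scalar(Ta, "Ta", nonneg = TRUE)
  check_scalar(Te, "Te", positive = TRUE)
  if (Ta > Te) stopf("accrual duration Ta = %g exceeds trial duration Te = %g",
                     Ta, Te)
  check_scalar(tau, "tau", positive = TRUE)
  if (tau > Te) stopf("tau = %g exceeds the trial duration Te = %g", tau, Te)
  check_prob(one.sided.alpha, "one.sided.alpha", open_left = TRUE,
             open_right = TRUE)
  if (!is.null(f1)) check_prob(f1, "f1", open_left = TRUE, open_right = TRUE)
  if (!is.null(f2)) check_prob(f2, "f2", open_left = TRUE, open_right = TRUE)
  if (!is.null(m0)) check_scalar(m0, "m0", positive = TRUE)
  if (xor(is.null(m0), is.null(f2)))
    stopf("margin option 2 needs both 'm0' and 'f2'")
  if (!is.null(margin)) check_scalar(margin, "margin", positive = TRUE)
  if (is.null(margin) && is.null(f1) && is.null(f2))
    stopf(paste0("no margin option: if no 'margin' is given, input either ",
                 "'f1' or ('m0', 'f2')"))
  if (!is.null(n) && round_half_up(r * n) < 2)
    stopf("experimental arm size round(r * n) = %d must be at least 2",
          round_half_up(r * n))
  check_scalar(n_simulations, "n_simulations", positive = TRUE,
               integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  # validates ps/rs/rhos/s.dist/TXswitch/af and the entry pattern
  sw <- switch_spec(s.dist, ps, rs, rhos, TXswitch, af)
  ent <- entry_spec(entry, Ta)
  if (!identical(censoring.prob, "AC.only")) {
    check_prob(censoring.prob, "censoring.prob", open_right = TRUE)
  }
  lossfu.dist <- match.arg(lossfu.dist, c("unif", "exp"))
  structure(list(n = if (is.null(n)) NULL else as.integer(n), r = r,
                 m1 = m1, m2 = m2, shape = shape, k = k,
                 f1 = f1, m0 = m0, f2 = f2, margin = margin,
                 ps = ps, rs = rs, rhos = rhos, s.dist = s.dist,
                 entry = ent$pattern, censoring.prob = censoring.prob,
                 lossfu.dist = lossfu.dist, Ta = Ta, Te = Te, tau = tau,
                 one.sided.alpha = one.sided.alpha, TXswitch = TXswitch,
                 af = af, n_simulations = as.integer(n_simulations),
                 seed = as.integer(seed)),
            class = "ni_design")
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

#' @export
print.ni_design <- function(x, ...) {
  cat("Non-inferiority trial design (DRMST, intention-to-treat)\n")
  n2 <- if (is.null(x$n)) NA_integer_ else round_half_up(x$r * x$n)
  cat(sprintf("  arms: n = %s control, %s experimental (r = %g)\n",
              if (is.null(x$n)) "<unset>" else x$n,
              ifelse(is.na(n2), "<unset>", n2), x$r))
  cat(sprintf("  event time: generalized gamma, medians m1 = %g, m2 = %g, shape = %g, k = %g\n",
              x$m1, x$m2, x$shape, x$k))
  mg <- if (!is.null(x$margin)) sprintf("numeric margin = %g", x$margin)
  else if (!is.null(x$f2)) sprintf("preserved DRMST fraction f2 = %g (m0 = %g)", x$f2, x$m0)
  else sprintf("preserved RMST fraction f1 = %g", x$f1)
  cat(sprintf("  margin: %s\n", mg))
  cat(sprintf("  switching: ps = %g, s.dist = %s, rs = %g, rhos = %g, direction %s, af = %g\n",
              x$ps, if (is.numeric(x$s.dist)) sprintf("fixed at %g", x$s.dist)
              else sprintf('"%s"', x$s.dist), x$rs, x$rhos, x$TXswitch, x$af))
  cat(sprintf("  follow-up: Ta = %g, Te = %g, tau = %g, entry = \"%s\"\n",
              x$Ta, x$Te, x$tau, x$entry))
  cat(sprintf("  censoring: %s (dropout family \"%s\")\n",
              if (identical(x$censoring.prob, "AC.only")) "administrative only"
              else sprintf("total control-arm probability %g", x$censoring.prob),
              x$lossfu.dist))
  cat(sprintf("  test: one-sided alpha = %g; %d simulations, seed %d\n",
              x$one.sided.alpha, x$n_simulations, x$seed))
  invisible(x)
}

# Solve every calibration of a design once: event-time laws, margin,
# dropout parameter, switch-time parameters and the acceleration factor.
solve_design <- function(design) {
  stopifnot(inherits(design, "ni_design"))
  spec1 <- gg_from_median(design$m1, design$shape, design$k)
  spec2 <- gg_from_median(design$m2, design$shape, design$k)
  entry <- entry_spec(design$entry, design$Ta)
  marg <- resolve_margin(design)
  R2 <- true_rmst(spec2, design$tau)
  if (marg$mode == "preserved_drmst" && R2 <= marg$R0)
    warnf(paste0("configured alternative violates the margin-option-2 side ",
                 "condition R2(tau) > R0(tau): R2 = %.6g <= R0 = %.6g"),
          R2, marg$R0)
  dropout <- if (identical(design$censoring.prob, "AC.only")) {
    dropout_spec("none", Te = design$Te)
  } else {
    solve_dropout_param(design$censoring.prob, spec1, entry, design$Te,
                        design$lossfu.dist)
  }
  to2 <- design$TXswitch == "1to2"
  accel <- design$af * if (to2) design$m2 / design$m1 else design$m1 / design$m2
  switch_arm_spec <- if (to2) spec1 else spec2
  sw <- NULL
  if (design$ps > 0) {
    sw <- solve_switch_params(
      switch_spec(design$s.dist, design$ps, design$rs, design$rhos,
                  design$TXswitch, design$af),
      switch_arm_spec)
  }
  list(spec1 = spec1, spec2 = spec2, entry = entry, dropout = dropout,
       margin = marg, delta = marg$delta, R1 = marg$R1, R2 = R2,
       accel = accel, switch = sw, switch_arm_spec = switch_arm_spec,
       n1 = design$n,
       n2 = if (is.null(design$n)) NULL else round_half_up(design$r * design$n))
}
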