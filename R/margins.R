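# Non-inferiority margin constructions on the DRMST scale.
#
# Three options: (1) preserve a fraction f1 of the control RMST,
# delta = (1 - f1) R1(tau); (2) preserve a fraction f2 of the RMST
# difference between control and a hypothetical placebo,
# delta = (1 - f2) (R1(tau) - R0(tau)); (3) convert a hazard-ratio margin
# 1/theta > 1 under proportional hazards,
# delta = R1(tau) - int_0^tau S1(t)^(1/theta) dt.

#' Margin as a preserved fraction of the control RMST
#'
#' @param f1 Preserved fraction in (0, 1).
#' @param R1 Control-arm RMST at the analysis horizon.
#' @return The margin \eqn{\delta = (1 - f_1) R_1(\tau)}.
#' @export
margin_preserved_rmst <- function(f1, R1) {
  check_prob(f1, "f1", open_left = TRUE, open_right = TRUE)
  check_scalar(R1, "R1", positive = TRUE)
  (1 - f1) * R1
}

#' Margin as a preserved fraction of the control-vs-placebo DRMST
#'
#' @param f2 Preserved fraction in (0, 1).
#' @param R1 Control-arm RMST.
#' @param R0 Hypothetical-placebo RMST; must be smaller than `R1`.
#' @return The margin \eqn{\delta = (1 - f_2)(R_1(\tau) - R_0(\tau))}.
#' @export
margin_preserved_drmst <- function(f2, R1, R0) {
  check_prob(f2, "f2", open_left = TRUE, open_right = TRUE)
  check_scalar(R1, "R1", positive = TRUE)
  check_scalar(R0, "R0", positive = TRUE)
  if (R1 <= R0)
    stopf(paste0("hypothetical placebo must be worse than active control ",
                 "(R1 = %.6g <= R0 = %.6g)"), R1, R0)
  (1 - f2) * (R1 - R0)
}

#' Margin converted from a hazard-ratio margin
#'
#' Under proportional hazards a survival curve with hazard ratio
#' `hr_margin` against the control is \eqn{S_1(t)^{\mathrm{hr}}}; the DRMST
#' margin is the RMST gap between the control curve and that boundary
#' curve.
#'
#' @param hr_margin Hazard-ratio non-inferiority margin \eqn{1/\theta > 1}.
#' @param control Control-arm [gg_spec()] law.
#' @param tau Analysis horizon.
#' @return The margin \eqn{\delta = R_1(\tau) - \int_0^\tau
#'   S_1(t)^{\mathrm{hr}}\,dt > 0}.
#' @examples
#' ctrl <- gg_from_median(47.8)
#' margin_from_hr(1.762, ctrl, tau = 5.75)   # 0.169
#' margin_from_hr(1.762, ctrl, tau = 10)     # 0.484
#' @export
margin_from_hr <- function(hr_margin, control, tau) {
  check_scalar(hr_margin, "hr_margin")
  if (hr_margin <= 1)
    stopf("'hr_margin' (= 1/theta) must exceed 1 (got %g)", hr_margin)
  stopifnot(inherits(control, "gg_spec"))
  check_scalar(tau, "tau", positive = TRUE)
  R1 <- true_rmst(control, tau)
  Rtheta <- stats::integrate(function(t) gg_survival(t, control)^hr_margin,
                             0, tau, abs.tol = 1e-10, rel.tol = 1e-10,
                             subdivisions = 500L)$value
  R1 - Rtheta
}

#' Resolve the margin option of a design
#'
#' Dispatches by precedence: an explicit numeric `margin` overrides the
#' preserved-DRMST option (`f2`, `m0`), which overrides the preserved-RMST
#' option (`f1`). When several options are supplied the overridden ones are
#' reported in the audit record; `f1` together with (`f2`, `m0`) is an
#' error unless the two resolved margins agree numerically.
#'
#' @param design An [ni_design()] object.
#' @return A list with elements `mode` (one of `"numeric"`,
#'   `"preserved_drmst"`, `"preserved_rmst"`), `delta`, `R1`, `R0` (`NA`
#'   unless mode 2) and `ignored` (character vector of overridden options).
#' @export
resolve_margin <- function(design) {
  stopifnot(inherits(design, "ni_design"))
  spec1 <- gg_from_median(design$m1, design$shape, design$k)
  R1 <- true_rmst(spec1, design$tau)
  has_num <- !is.null(design$margin)
  has_f2 <- !is.null(design$f2) && !is.null(design$m0)
  has_f1 <- !is.null(design$f1)
  if (!has_num && !has_f2 && !has_f1)
    stopf(paste0("no margin option supplied: provide a numeric 'margin', ",
                 "or 'f1', or ('m0', 'f2')"))
  R0 <- NA_real_
  if (has_f2) {
    spec0 <- gg_from_median(design$m0, design$shape, design$k)
    R0 <- true_rmst(spec0, design$tau)
  }
  ignored <- character()
  if (has_num) {
    check_scalar(design$margin, "margin", positive = TRUE)
    if (has_f2) ignored <- c(ignored, "(m0, f2)")
    if (has_f1) ignored <- c(ignored, "f1")
    if (length(ignored))
      warnf("numeric 'margin' overrides %s", paste(ignored, collapse = " and "))
    return(list(mode = "numeric", delta = design$margin, R1 = R1, R0 = R0,
                ignored = ignored))
  }
  if (has_f2) {
    delta <- margin_preserved_drmst(design$f2, R1, R0)
    if (has_f1) {
      d1 <- margin_preserved_rmst(design$f1, R1)
      if (abs(d1 - delta) > 1e-9)
        stopf(paste0("conflicting margin options: f1 gives delta = %.9g but ",
                     "(m0, f2) gives delta = %.9g; supply only one"),
              d1, delta)
      ignored <- "f1"
      warnf("'f1' ignored in favour of the equivalent ('m0', 'f2') option")
    }
    return(list(mode = "preserved_drmst", delta = delta, R1 = R1, R0 = R0,
                ignored = ignored))
  }
  list(mode = "preserved_rmst", delta = margin_preserved_rmst(design$f1, R1),
       R1 = R1, R0 = R0, ignored = ignored)
}
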