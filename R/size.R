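# Sample-size determination: Monte-Carlo powers on a sample-size grid,
# monotone smoothing of the power curve, and inversion at the target
# power.

#' Fit a monotone nondecreasing power curve
#'
#' Smooths raw Monte-Carlo powers over a sample-size grid with a
#' monotone-constrained penalized cubic regression spline
#' (`mgcv::smoothCon` + `mono.con` + `pcls`, smoothing parameter taken
#' from the unconstrained fit) and evaluates the fit on every integer of
#' the grid range, clipped to [0, 1]. With fewer than four grid points
#' (or a degenerate spline fit) it falls back to isotonic regression with
#' monotone linear interpolation, with a warning.
#'
#' @param ns Integer grid of control-arm sample sizes (length >= 2).
#' @param powers Raw Monte-Carlo powers in [0, 1], one per grid point.
#' @return An object of class `"power_curve"`: data frame `curve` with
#'   columns `n` (integers spanning the grid) and `power` (fitted,
#'   nondecreasing), plus the raw points.
#' @export
fit_monotone_curve <- function(ns, powers) {
  if (length(ns) != length(powers) || length(ns) < 2)
    stopf("'ns' and 'powers' must have equal length >= 2")
  if (any(powers < 0 | powers > 1)) stopf("'powers' must lie in [0, 1]")
  o <- order(ns)
  ns <- as.integer(ns[o])
  powers <- powers[o]
  grid <- seq(min(ns), max(ns))
  fit <- NULL
  method <- "pcls"
  if (length(ns) >= 4) {
    fit <- tryCatch(monotone_spline_fit(ns, powers, grid),
                    error = function(e) NULL)
  }
  if (is.null(fit)) {
    if (length(ns) >= 4)
      warnf("monotone spline fit failed; falling back to isotonic regression")
    else
      warnf("fewer than 4 grid points; using isotonic regression instead of a spline")
    iso <- stats::isoreg(ns, powers)
    fit <- stats::approx(ns, iso$yf, xout = grid, rule = 2)$y
    method <- "isotonic"
  }
  fit <- pmin(pmax(fit, 0), 1)
  fit <- cummax(fit)  # guard against numerically tiny violations
  structure(list(curve = data.frame(n = grid, power = fit),
                 ns = ns, powers = powers, method = method),
            class = "power_curve")
}

monotone_spline_fit <- function(ns, powers, grid) {
  dat <- data.frame(x = as.numeric(ns), y = powers)
  kk <- max(4L, min(length(ns) - 1L, 10L))
  sm <- mgcv::smoothCon(mgcv::s(x, k = kk, bs = "cr"), dat, knots = NULL,
                        absorb.cons = FALSE)[[1]]
  con <- mgcv::mono.con(sm$xp)
  sp <- mgcv::gam(y ~ s(x, k = kk, bs = "cr"), data = dat)$sp
  # cr-basis coefficients are the spline values at the knots xp, so a
  # strictly increasing start is feasible under the monotone constraints
  G <- list(X = sm$X, C = matrix(0, 0, 0), sp = sp,
            p = seq(min(powers), max(powers) + 1e-4,
                    length.out = length(sm$xp)),
            y = powers, w = rep(1, length(powers)),
            Ain = con$A, bin = con$b, S = sm$S, off = 0)
  p <- mgcv::pcls(G)
  drop(mgcv::Predict.matrix(sm, data.frame(x = grid)) %*% p)
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Monotone power curve (%s) over n = %d..%d from %d grid points\n",
              x$method, min(x$curve$n), max(x$curve$n), length(x$ns)))
  invisible(x)
}

#' Required sample size for a target power
#'
#' Evaluates the Monte-Carlo power at the `B + 1` grid points
#' `nL + j * w`, `w = round((nU - nL) / B)`, fits a monotone nondecreasing
#' power curve ([fit_monotone_curve()]) and returns the smallest integer
#' control-arm size whose fitted power reaches the target `epwr`. The
#' adjusted margin is re-estimated at every grid size. Each grid point
#' uses its own seed (`seed + j`) so grid evaluations are independent.
#'
#' @param design An [ni_design()] object (its `n` is ignored);
#'   alternatively pass design parameters through `...`.
#' @param ... Design parameters when `design` is not supplied.
#' @param nL,nU Minimum and maximum control-arm sizes to explore
#'   (`nL < nU`).
#' @param B Number of intervals splitting `[nL, nU]` (at least 2).
#'   Default 10.
#' @param epwr Target power. Default 0.8.
#' @param adjusted Use the switching-adjusted margin (default).
#' @return An object of class `"ni_size"`: `n_required`, the grid with
#'   raw and fitted powers, expected event counts and margins per grid
#'   point, and the fitted [fit_monotone_curve()] object.
#' @examples
#' \donttest{
#' s <- calculate_size(m1 = 1, m2 = 1.1, m0 = 0.5, f2 = 0.5, ps = 0,
#'                     Ta = 3, Te = 5, censoring.prob = 0.2,
#'                     nL = 100, nU = 250, B = 5, n_simulations = 200)
#' s
#' plot(s)
#' }
#' @export
calculate_size <- function(design = NULL, ..., nL, nU, B = 10, epwr = 0.8,
                           adjusted = TRUE) {
  if (is.null(design)) design <- ni_design(...)
  stopifnot(inherits(design, "ni_design"))
  check_scalar(nL, "nL", positive = TRUE, integer = TRUE)
  check_scalar(nU, "nU", positive = TRUE, integer = TRUE)
  if (nL >= nU) stopf("'nL' (= %d) must be smaller than 'nU' (= %d)", nL, nU)
  check_scalar(B, "B", positive = TRUE, integer = TRUE)
  if (B < 2) stopf("'B' must be at least 2")
  check_prob(epwr, "epwr", open_left = TRUE, open_right = TRUE)
  w <- round((nU - nL) / B)
  ns <- unique(as.integer(nL + (0:B) * w))
  results <- vector("list", length(ns))
  for (j in seq_along(ns)) {
    d <- design
    d$n <- ns[j]
    d$seed <- design$seed + j - 1L
    results[[j]] <- calculate_power(d, adjusted = adjusted)
  }
  powers <- vapply(results, function(x) x$power, numeric(1))
  curve <- fit_monotone_curve(ns, powers)
  fitted <- curve$curve
  if (utils::tail(fitted$power, 1) < epwr)
    stopf(paste0("fitted power %.3f at nU = %d is below the target %.2f; ",
                 "increase 'nU'"), utils::tail(fitted$power, 1), max(ns), epwr)
  n_required <- fitted$n[which(fitted$power >= epwr)[1]]
  if (fitted$power[1] >= epwr) {
    warnf(paste0("fitted power %.3f already meets the target %.2f at nL = %d; ",
                 "consider a smaller 'nL'"), fitted$power[1], epwr, nL)
    n_required <- ns[1]
  }
  grid_tab <- data.frame(
    n = ns, power = powers,
    fitted = fitted$power[match(ns, fitted$n)],
    E1 = vapply(results, function(x) x$E1, numeric(1)),
    E2 = vapply(results, function(x) x$E2, numeric(1)),
    delta = vapply(results, function(x) x$delta, numeric(1)),
    delta_star = vapply(results, function(x) x$delta_star, numeric(1)))
  structure(list(n_required = as.integer(n_required), epwr = epwr,
                 grid = grid_tab, curve = curve,
                 nL = as.integer(nL), nU = as.integer(nU), B = as.integer(B),
                 w = w, adjusted = adjusted,
                 delta = results[[1]]$delta,
                 delta_star_grid = grid_tab$delta_star,
                 n_simulations = design$n_simulations, seed = design$seed,
                 alpha = design$one.sided.alpha, r = design$r,
                 design = design, grid_results = results),
            class = "ni_size")
}

#' @export
print.ni_size <- function(x, ...) {
  cat("Sample-size determination, DRMST non-inferiority test (ITT)\n")
  cat(sprintf("  grid: n = %d..%d in %d intervals (w = %d); %d simulations per point\n",
              x$nL, x$nU, x$B, x$w, x$n_simulations))
  cat(sprintf("  required control-arm n = %d for target power %.2f (one-sided alpha %g)\n",
              x$n_required, x$epwr, x$alpha))
  cat(sprintf("  experimental arm: round(r * n) = %d (r = %g); total %d\n",
              round_half_up(x$r * x$n_required), x$r,
              x$n_required + round_half_up(x$r * x$n_required)))
  cat("\n  grid powers:\n")
  print(format(x$grid, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
summary.ni_size <- function(object, ...) {
  out <- object[c("n_required", "epwr", "grid", "nL", "nU", "B", "w",
                  "n_simulations", "seed", "alpha", "adjusted")]
  class(out) <- "summary.ni_size"
  out
}

#' @export
print.summary.ni_size <- function(x, ...) {
  cat(sprintf("required n = %d (target power %.2f, alpha %g)\n",
              x$n_required, x$epwr, x$alpha))
  print(format(x$grid, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Fitted power at a given sample size
#'
#' @param object An `"ni_size"` result.
#' @param n Integer sample sizes within the evaluated grid range.
#' @param ... Unused.
#' @export
predict.ni_size <- function(object, n, ...) {
  crv <- object$curve$curve
  if (any(n < min(crv$n) | n > max(crv$n)))
    stopf("'n' outside the evaluated grid range %d..%d", min(crv$n), max(crv$n))
  crv$power[match(round(n), crv$n)]
}

#' Plot the Monte-Carlo powers and the fitted monotone curve
#'
#' @param x An `"ni_size"` result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ni_size <- function(x, ...) {
  crv <- x$curve$curve
  graphics::plot(x$grid$n, x$grid$power, xlab = "control-arm sample size n",
                 ylab = "power", ylim = range(c(x$grid$power, x$epwr, crv$power)),
                 pch = 19, ...)
  graphics::lines(crv$n, crv$power, col = "steelblue", lwd = 2)
  graphics::abline(h = x$epwr, lty = 2, col = "grey40")
  graphics::abline(v = x$n_required, lty = 3, col = "firebrick")
  graphics::legend("bottomright",
                   legend = c("Monte-Carlo power", "monotone fit",
                              sprintf("target %.2f", x$epwr),
                              sprintf("required n = %d", x$n_required)),
                   pch = c(19, NA, NA, NA), lty = c(NA, 1, 2, 3),
                   col = c("black", "steelblue", "grey40", "firebrick"),
                   bty = "n", cex = 0.85)
  invisible(x)
}
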