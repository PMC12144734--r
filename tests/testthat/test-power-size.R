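# Adjusted margin, Monte-Carlo power, monotone power curve and the
# sample-size search.

quick_design <- function(...) {
  args <- list(n = 80, m1 = 1, m2 = 1.1, m0 = 0.5, f2 = 0.5,
               Ta = 3, Te = 5, censoring.prob = 0.2, n_simulations = 300,
               seed = 501)
  args <- utils::modifyList(args, list(...))
  do.call(ni_design, args)
}

test_that("adjusted margin collapses to delta when switching cannot bite", {
  a0 <- estimate_adjusted_margin(quick_design(ps = 0))
  expect_identical(a0$delta_star, a0$delta)
  expect_true(is.na(a0$R_mixed))
  # m1 = m2 and af = 1 gives acceleration exactly 1
  a1 <- estimate_adjusted_margin(ni_design(n = 80, m1 = 1, m2 = 1, f1 = 0.8,
                                           ps = 0.5, Ta = 0, Te = 5,
                                           n_simulations = 300))
  expect_identical(a1$delta_star, a1$delta)
})

test_that("adjusted margin shifts in the direction of the switching benefit", {
  # control switchers adopting a worse regimen lower the mixed RMST
  a_worse <- estimate_adjusted_margin(quick_design(m2 = 0.8, ps = 0.4,
                                                   n_simulations = 400))
  expect_lt(a_worse$delta_star, a_worse$delta)
  expect_lt(a_worse$R_mixed, a_worse$R_pure)
  # and a better regimen raises it
  a_better <- estimate_adjusted_margin(quick_design(ps = 0.4,
                                                    n_simulations = 400))
  expect_gt(a_better$delta_star, a_better$delta)
})

test_that("power results are reproducible and carry event counts", {
  d <- quick_design(ps = 0.2, m2 = 0.9)
  p1 <- calculate_power(d)
  p2 <- calculate_power(d)
  expect_identical(p1$power, p2$power)
  expect_identical(p1$E1, p2$E1)
  expect_lte(p1$E1, d$n)
  expect_lte(p1$E2, rmstni:::round_half_up(d$r * d$n))
  expect_gte(p1$power, 0)
  expect_lte(p1$power, 1)
})

test_that("an enormous margin forces rejection in every simulation", {
  p <- calculate_power(quick_design(margin = 50, m0 = NULL, f2 = NULL,
                                    ps = 0, n_simulations = 100))
  expect_equal(p$power, 1)
})

test_that("power increases with sample size and with the experimental median", {
  d_small <- quick_design(ps = 0, n_simulations = 600)
  d_large <- quick_design(ps = 0, n_simulations = 600)
  d_large$n <- 250L
  p_small <- calculate_power(d_small)$power
  p_large <- calculate_power(d_large)$power
  expect_gt(p_large, p_small + 0.05)
  p_worse <- calculate_power(quick_design(m2 = 0.95, ps = 0,
                                          n_simulations = 600))$power
  expect_gt(p_small, p_worse)
})

test_that("monotone curve smooths raw powers without leaving their band", {
  ns <- seq(100, 250, by = 15)
  set.seed(502)
  truth <- pnorm((ns - 140) / 60)
  raw <- pmin(1, pmax(0, truth + rnorm(length(ns), 0, 0.008)))
  fit <- fit_monotone_curve(ns, raw)
  expect_true(all(diff(fit$curve$power) >= -1e-9))
  at_grid <- fit$curve$power[match(ns, fit$curve$n)]
  expect_lt(max(abs(at_grid - raw)), 3 * 0.01)
  # constant input stays constant; a small dip is ironed out
  flat <- fit_monotone_curve(ns, rep(0.5, length(ns)))
  expect_true(all(abs(flat$curve$power - 0.5) < 1e-6))
  dip <- raw
  dip[5] <- dip[4] - 0.01
  fdip <- fit_monotone_curve(ns, dip)
  expect_true(all(diff(fdip$curve$power) >= -1e-9))
})

test_that("tiny grids fall back to isotonic interpolation with a warning", {
  expect_warning(fit <- fit_monotone_curve(c(100, 150, 200), c(0.5, 0.4, 0.9)),
                 "isotonic")
  expect_true(all(diff(fit$curve$power) >= -1e-9))
})

test_that("size search inverts the fitted curve and validates its bounds", {
  d <- quick_design(ps = 0)
  s <- calculate_size(d, nL = 60, nU = 220, B = 4, epwr = 0.7)
  expect_s3_class(s, "ni_size")
  expect_gte(s$n_required, 60)
  expect_lte(s$n_required, 220)
  expect_gte(predict(s, s$n_required), 0.7)
  if (s$n_required > 60) expect_lt(predict(s, s$n_required - 1), 0.7)
  expect_error(calculate_size(d, nL = 100, nU = 100, B = 4), "smaller")
  expect_error(calculate_size(d, nL = 60, nU = 220, B = 4, epwr = 0.999),
               "increase 'nU'")
  expect_warning(calculate_size(d, nL = 150, nU = 260, B = 4, epwr = 0.2),
                 "smaller 'nL'")
})

test_that("switching with the adjusted margin barely moves the required size", {
  d <- ni_design(m1 = 1, m2 = 1.1, m0 = 0.5, f2 = 0.5, Ta = 3, Te = 5,
                 censoring.prob = 0.2, n_simulations = 1000, seed = 503)
  s_ns <- calculate_size(d, nL = 110, nU = 210, B = 5, epwr = 0.8)
  d_sw <- d
  d_sw$ps <- 0.2
  s_sw <- calculate_size(d_sw, nL = 110, nU = 210, B = 5, epwr = 0.8)
  expect_gt(s_sw$n_required / s_ns$n_required, 0.93)
  expect_lt(s_sw$n_required / s_ns$n_required, 1.07)
})

test_that("reverse-direction switching mirrors the margin adjustment", {
  d <- quick_design(ps = 0.3, m2 = 0.9, TXswitch = "2to1",
                    n_simulations = 400)
  a <- estimate_adjusted_margin(d)
  # experimental switchers adopt the better control regimen: R2* > R2,
  # so the adjustment shrinks the margin
  expect_lt(a$delta_star, a$delta)
  p <- calculate_power(d)
  expect_s3_class(p, "ni_power")
})
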