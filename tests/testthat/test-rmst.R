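# Kaplan-Meier fit, restricted-mean estimation with variance, and the
# one-sided DRMST non-inferiority test.

test_that("product-limit fit matches hand computations", {
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n.risk, c(3, 2, 1))
  # no events: flat at 1
  km0 <- km_fit(c(1, 2, 3), c(0, 0, 0))
  expect_length(km0$time, 0)
  expect_false(km0$maxtime_event)
  # middle observation censored
  km2 <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv, c(2 / 3, 0))
  expect_error(km_fit(numeric(0), numeric(0)), "length")
  expect_error(km_fit(c(-1, 2), c(1, 1)), "positive")
})

test_that("product-limit fit agrees with the brute-force oracle on random data", {
  set.seed(401)
  for (rep in 1:60) {
    n <- sample(4:20, 1)
    dat <- random_surv_data(n, tie_grid = if (rep %% 2) seq(0.5, 5, by = 0.5))
    if (!any(dat$event > 0)) dat$event[1] <- 1
    km <- km_fit(dat$time, dat$event)
    s_pkg <- km$surv
    s_orc <- km_oracle(dat$time, dat$event, km$time)
    expect_equal(s_pkg, s_orc, tolerance = 1e-12)
  }
})

test_that("restricted mean equals the censored-area oracle and the no-censoring mean", {
  expect_equal(rmst_km(c(1, 2, 3), c(1, 1, 1), 3)$estimate, 2.0)
  set.seed(402)
  for (rep in 1:25) {
    dat <- random_surv_data(sample(5:40, 1))
    if (!any(dat$event > 0)) dat$event[1] <- 1
    tau <- runif(1, 0.5, 2)
    got <- suppressWarnings(rmst_km(dat$time, dat$event, tau))
    expect_equal(got$estimate, rmst_oracle(dat$time, dat$event, tau),
                 tolerance = 1e-10)
  }
  # with no censoring, RMST is exactly the sample mean of min(T, tau)
  set.seed(403)
  tt <- rexp(500)
  expect_equal(rmst_km(tt, rep(1, 500), 1.2)$estimate, mean(pmin(tt, 1.2)),
               tolerance = 1e-12)
  # no events by tau: estimate tau, variance 0
  r0 <- suppressWarnings(rmst_km(c(1, 2), c(0, 0), 5))
  expect_equal(r0$estimate, 5)
  expect_equal(r0$variance, 0)
})

test_that("estimate and variance match the survival package on censored data", {
  skip_if_not_installed("survival")
  set.seed(404)
  for (rep in 1:10) {
    n <- 150
    tt <- pmin(rexp(n), runif(n, 0.2, 3))
    ev <- as.numeric(rexp(n) > tt) * rbinom(n, 1, 0.9)
    if (!any(ev > 0)) ev[1] <- 1
    tau <- 1.4
    tab <- summary(survival::survfit(survival::Surv(tt, ev) ~ 1),
                   rmean = tau)$table
    got <- suppressWarnings(rmst_km(tt, ev, tau))
    expect_equal(got$estimate, unname(tab["rmean"]), tolerance = 1e-10)
    expect_equal(sqrt(got$variance), unname(tab["se(rmean)"]),
                 tolerance = 1e-10)
  }
})

test_that("rmst variance tracks the replicate variance of the estimator", {
  set.seed(405)
  ev_law <- gg_from_median(1)
  nrep <- 1000
  n <- 10000
  est <- numeric(nrep)
  vhat <- numeric(nrep)
  for (i in seq_len(nrep)) {
    tt <- gg_sample(n, ev_law)
    cc <- pmin(runif(n, 0, 8), 5)
    y <- pmin(tt, cc)
    core <- rmstni:::rmst_core(y, tt <= cc, 4)
    est[i] <- core[1]
    vhat[i] <- core[2]
  }
  expect_lt(abs(mean(vhat) - var(est)) / var(est), 0.10)
})

test_that("rmst estimation is invariant to record order", {
  set.seed(406)
  dat <- random_surv_data(60)
  dat$event[1] <- 1
  o <- sample(60)
  a <- suppressWarnings(rmst_km(dat$time, dat$event, 1.5))
  b <- suppressWarnings(rmst_km(dat$time[o], dat$event[o], 1.5))
  expect_identical(a$estimate, b$estimate)
  expect_identical(a$variance, b$variance)
})

test_that("non-inferiority decision follows the lower-bound rule", {
  mk <- function(est2, est1, v) {
    # two-arm data engineered via direct arithmetic on the test statistic
    drmst_arith <- (est2 - est1) - qnorm(0.975) * sqrt(v)
    drmst_arith
  }
  # z-quantile arithmetic: lb = 0 - 1.96 * 0.1 = -0.196 > -0.3
  expect_equal(qnorm(0.975), 1.95996, tolerance = 1e-5)
  expect_gt(mk(0, 0, 0.01), -0.3)
  # identical arms: estimate 0, lower bound negative, tiny margin fails
  d <- data.frame(time = c(1, 2, 1, 2), event = c(1, 1, 1, 1),
                  arm = factor(rep(c("control", "experimental"), each = 2)))
  res <- drmst_test(d, tau = 2, margin = 1e-9, alpha = 0.025)
  expect_equal(res$estimate, 0)
  expect_false(res$reject)
  res2 <- drmst_test(d, tau = 2, margin = 5, alpha = 0.025)
  expect_true(res2$reject)   # enormous margin always rejects
  # degenerate SE with the estimate exactly at -margin: strict inequality
  # means no rejection
  d3 <- data.frame(time = c(1, 1, 0.5, 0.5), event = rep(1, 4),
                   arm = factor(rep(c("control", "experimental"), each = 2)))
  res3 <- drmst_test(d3, tau = 2, margin = 0.5, alpha = 0.025)
  expect_equal(res3$se, 0)
  expect_equal(res3$lower, -0.5)
  expect_false(res3$reject)
})

test_that("the standalone test consumes exported trial tables", {
  d <- ni_design(n = 300, m1 = 1, m2 = 1.1, m0 = 0.5, f2 = 0.5, ps = 0,
                 Ta = 3, Te = 5, censoring.prob = 0.2, seed = 407)
  tr <- simulate_trial(d)
  f <- tempfile(fileext = ".tsv")
  write_trial(tr, f)
  res <- drmst_test(read_trial(f), tau = 5, margin = 0.3)
  expect_s3_class(res, "drmst_test")
  expect_equal(res$estimate, res$rmst_experimental - res$rmst_control)
  expect_identical(res$reject, res$lower > -0.3)
  unlink(f)
})
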