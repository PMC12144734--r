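# Independent oracles used across the suite. Deliberately naive
# implementations: correctness over speed, and no shared code with the
# package internals they check.

# Product-limit survival estimate at each point of `tgrid`, computed by
# direct counting (events-first at ties).
km_oracle <- function(time, event, tgrid) {
  ev_times <- sort(unique(time[event > 0]))
  vapply(tgrid, function(tt) {
    s <- 1
    for (u in ev_times[ev_times <= tt]) {
      at_risk <- sum(time >= u)
      d <- sum(time == u & event > 0)
      s <- s * (1 - d / at_risk)
    }
    s
  }, numeric(1))
}

# Area under the oracle KM curve on [0, tau] by fine trapezoid-free
# stepwise summation over the jump points.
rmst_oracle <- function(time, event, tau) {
  jumps <- sort(unique(c(0, time[event > 0 & time <= tau], tau)))
  s <- km_oracle(time, event, jumps)
  sum(s[-length(s)] * diff(jumps))
}

# Random censored dataset, optionally on a coarse grid to force ties.
random_surv_data <- function(n, tie_grid = NULL) {
  t_raw <- if (is.null(tie_grid)) rexp(n, 1)
  else sample(tie_grid, n, replace = TRUE)
  list(time = t_raw, event = rbinom(n, 1, 0.6))
}

expect_close <- function(object, expected, tol, label = NULL) {
  expect_lt(abs(object - expected), tol, label = label)
}

# Analytic entry-time CDFs, re-derived from the linear densities.
entry_cdf_ref <- function(v, pattern, Ta) {
  switch(pattern,
         decreasing = 2 * v / Ta - (v / Ta)^2,
         unif = v / Ta,
         increasing = (v / Ta)^2)
}
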