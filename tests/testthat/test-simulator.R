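# Trial-level simulation: allocation, purity without switching,
# censoring calibration and reproducibility.

base_design <- function(...) {
  args <- list(n = 100, m1 = 1, m2 = 1.1, m0 = 0.5, f2 = 0.5,
               Ta = 3, Te = 5, censoring.prob = 0.2)
  args <- utils::modifyList(args, list(...))
  do.call(ni_design, args)
}

test_that("arm counts are exact and experimental size rounds half away from zero", {
  tr <- simulate_trial(base_design(r = 2))
  expect_identical(as.vector(table(tr$arm)), c(100L, 200L))
  tr2 <- simulate_trial(ni_design(n = 101, r = 1.5, m1 = 1, m2 = 1, f1 = 0.8,
                                  Ta = 0, Te = 5))
  expect_identical(sum(tr2$arm == "experimental"), 152L)  # 151.5 rounds up
})

test_that("without switching both arms are pure samples of their laws", {
  d <- base_design(ps = 0)
  tr <- simulate_trial(d)
  expect_false(any(tr$switched))
  expect_true(all(is.na(tr$switch_time)))
  expect_identical(tr$latent, tr$counterfactual)
})

test_that("switching appears only in the designated arm and respects eligibility", {
  d <- base_design(ps = 0.9, m2 = 0.8, s.dist = "gamma", n = 400)
  tr <- simulate_trial(d)
  expect_false(any(tr$switched[tr$arm == "experimental"]))
  sw <- tr$switched
  expect_gt(sum(sw), 0)
  expect_true(all(tr$switch_time[sw] < tr$latent[sw]))
  # counterfactual applies the RPSFT stretch
  expect_equal(tr$counterfactual[sw],
               tr$switch_time[sw] + (tr$latent[sw] - tr$switch_time[sw]) * 0.8,
               tolerance = 1e-12)
  d2 <- base_design(ps = 0.9, m2 = 0.8, TXswitch = "2to1", n = 400)
  tr2 <- simulate_trial(d2)
  expect_false(any(tr2$switched[tr2$arm == "control"]))
})

test_that("identity acceleration leaves switchers' event times unchanged", {
  d <- ni_design(n = 300, m1 = 1, m2 = 1, f1 = 0.8, ps = 0.5,
                 Ta = 0, Te = 5, af = 1)
  tr <- simulate_trial(d)
  expect_gt(sum(tr$switched), 0)
  expect_identical(tr$latent, tr$counterfactual)
})

test_that("observed records satisfy the censoring identities", {
  tr <- simulate_trial(base_design(ps = 0.3, m2 = 0.9))
  expect_equal(tr$time, pmin(tr$counterfactual, tr$censor))
  expect_identical(tr$event, tr$counterfactual <= tr$censor)
  expect_true(all(tr$time > 0))
  expect_true(all(tr$time <= 5 - tr$entry + 1e-12))
})

test_that("administrative-only censoring with immediate accrual matches the law", {
  d <- ni_design(n = 5000, m1 = 1, m2 = 1, f1 = 0.8, ps = 0, Ta = 0, Te = 5,
                 n_simulations = 10, seed = 301)
  tr <- simulate_trial(d)
  expect_true(all(tr$censor == 5))
  ctrl <- tr$arm == "control"
  expect_equal(mean(tr$event[ctrl]), 1 - gg_survival(5, gg_from_median(1)),
               tolerance = 0.02)
})

test_that("control-arm censoring fraction matches the calibration target", {
  d <- ni_design(n = 20000, m1 = 1, m2 = 1.1, m0 = 0.5, f2 = 0.5, ps = 0,
                 Ta = 3, Te = 5, censoring.prob = 0.2, seed = 302)
  tr <- simulate_trial(d)
  frac <- 1 - mean(tr$event[tr$arm == "control"])
  expect_equal(frac, 0.2, tolerance = 3 * sqrt(0.2 * 0.8 / 20000) + 0.002)
})

test_that("simulation is bit-identical under a fixed seed", {
  d <- base_design(ps = 0.4, m2 = 0.9, seed = 303)
  tr1 <- simulate_trial(d)
  tr2 <- simulate_trial(d)
  expect_identical(tr1, tr2)
  tr3 <- simulate_trial(base_design(ps = 0.4, m2 = 0.9, seed = 304))
  expect_false(identical(tr1$time, tr3$time))
})

test_that("KM restricted mean of a large pure arm converges to the law's value", {
  d <- ni_design(n = 1e5, m1 = 1, m2 = 1, f1 = 0.8, ps = 0, Ta = 3, Te = 5,
                 censoring.prob = 0.2)
  solved <- rmstni:::solve_design(d)
  truth <- true_rmst(solved$spec1, 5)
  set.seed(305)
  est <- replicate(5, {
    a <- rmstni:::sim_arm(1e5, solved$spec1, solved$entry, solved$dropout)
    rmstni:::rmst_core(a$time, a$event, 5)[1]
  })
  # averaged over replicates so the Monte-Carlo noise sits well inside
  # the 0.5% consistency band
  expect_lt(abs(mean(est) - truth) / truth, 0.005)
})

test_that("trial tables round-trip through the TSV exporter", {
  tr <- simulate_trial(base_design(ps = 0.5, m2 = 0.9))
  f <- tempfile(fileext = ".tsv")
  write_trial(tr, f)
  back <- read_trial(f)
  expect_identical(names(back),
                   c("arm", "entry", "time", "event", "switched", "switch_time"))
  expect_equal(back$time, tr$time, tolerance = 1e-12)
  expect_identical(as.character(back$arm), as.character(tr$arm))
  unlink(f)
})
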