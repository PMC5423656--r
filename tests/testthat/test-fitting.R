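# Synthetic-data generation and GA parameter estimation.

wt <- clock_params()

test_that("synthetic datasets are reproducible, noise-free on the curve, noise-calibrated", {
  ds0 <- generate_synthetic(wt, times = seq(0, 40, 4), noise_sd = 0,
                            seed = 5)
  # zero noise: points lie on the normalized trace, inside [0, 1]
  expect_true(all(ds0$value >= 0 & ds0$value <= 1))
  ds0b <- generate_synthetic(wt, times = seq(0, 40, 4), noise_sd = 0,
                             seed = 99)
  expect_identical(ds0$value, ds0b$value)   # seed irrelevant at zero noise

  ds1 <- generate_synthetic(wt, times = seq(0, 99, 1), noise_sd = 0.05,
                            seed = 7)
  ds2 <- generate_synthetic(wt, times = seq(0, 99, 1), noise_sd = 0.05,
                            seed = 7)
  expect_identical(ds1$value, ds2$value)    # bit-identical under a seed
  clean <- generate_synthetic(wt, times = seq(0, 99, 1), noise_sd = 0,
                              seed = 7)
  resid <- ds1$value - clean$value
  # empirical residual sd within 30% of nominal (clipping shaves a little)
  expect_gt(stats::sd(resid), 0.05 * 0.7)
  expect_lt(stats::sd(resid), 0.05 * 1.3)
})

test_that("generator refuses arrhythmic parameters", {
  dead <- apply_mutant(wt, "per1_per2")
  expect_error(generate_synthetic(dead, times = 0:10), "arrhythmic")
})

test_that("objective is near zero for the generating parameters and penalizes arrhythmia", {
  ds <- generate_synthetic(wt, times = seq(0, 46, 2), noise_sd = 0)
  expect_lt(clock_objective(wt, ds), 1e-4)
  dead <- apply_mutant(wt, "bmal1")
  expect_gte(clock_objective(dead, ds), 100)
})

test_that("objective is invariant to a uniform time shift of the dataset", {
  ds <- generate_synthetic(wt, times = seq(0, 46, 2), noise_sd = 0)
  # shifting the sampling grid by +3 h changes the observed values, but the
  # phase-aligned objective judges the same parameters equally well
  ds3 <- generate_synthetic(wt, times = seq(0, 46, 2) + 3, noise_sd = 0)
  ds3$time <- ds3$time - 3
  c0 <- clock_objective(wt, ds)
  c3 <- clock_objective(wt, ds3)
  expect_lt(abs(c0 - c3), 1e-4)
})

test_that("GA is deterministic under a seed, elitist, and respects zero generations", {
  ds <- generate_synthetic(wt, times = seq(0, 46, 2), noise_sd = 0)
  free <- c("vs1", "vs2")
  truth <- as.numeric(wt[free])
  lower <- setNames(truth * 0.5, free)
  upper <- setNames(truth * 1.5, free)
  cfg <- list(pop_size = 6, generations = 3, seed = 11)
  f1 <- fit_ga(ds, free, lower, upper, start = wt, config = cfg)
  f2 <- fit_ga(ds, free, lower, upper, start = wt, config = cfg)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$history, f2$history)
  # elitism: best cost never increases
  expect_true(all(diff(f1$history) <= 0))
  # zero generations: best of the seeded initial population
  f0 <- fit_ga(ds, free, lower, upper, start = wt,
               config = list(pop_size = 6, generations = 0, seed = 11))
  expect_equal(length(f0$history), 1)
  expect_identical(f0$history[1], f1$history[1])
})

test_that("GA input validation", {
  ds <- generate_synthetic(wt, times = seq(0, 24, 4), noise_sd = 0)
  expect_error(fit_ga(ds, "vs1", lower = c(vs1 = 2), upper = c(vs1 = 1)),
               "bounds")
  expect_error(fit_ga(ds, "vs1", lower = c(vs1 = 0.1), upper = c(vs1 = 1),
                      config = list(crossover_rate = 2)), "rates")
})
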