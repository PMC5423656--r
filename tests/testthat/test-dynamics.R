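# Peak detection, period estimation, rhythmicity classes, normalization and
# time conventions.

make_traj <- function(t, x, transient = 0, var = "Mp1") {
  tb <- tibble::tibble(time = t)
  for (v in clock_state_names()) tb[[v]] <- 0
  tb[[var]] <- x
  structure(tb, class = c("clock_traj", class(tb)), transient = transient)
}

test_that("peak detection recovers cosine peaks to sub-sample precision", {
  t <- seq(0, 120, by = 0.01)
  tr <- make_traj(t, cos(2 * pi * t / 23.75))
  pk <- detect_peaks(tr, "Mp1")
  expect_equal(pk$time, seq(0, 120, by = 23.75)[-1][seq_len(nrow(pk))],
               tolerance = 1e-4, ignore_attr = TRUE)
  per <- estimate_period(pk)
  expect_equal(per$period, 23.75, tolerance = 1e-5)
  expect_lt(per$period_sd, 1e-4)
})

test_that("constant and shallow-ripple traces yield no peaks", {
  t <- seq(0, 100, by = 0.05)
  expect_equal(nrow(detect_peaks(make_traj(t, rep(1, length(t))), "Mp1")), 0)
  # ripple below the 1% prominence floor riding on a big pulse
  x <- 5 * exp(-(t - 50)^2 / 8) + 0.001 * sin(2 * pi * t)
  pk <- detect_peaks(make_traj(t, x), "Mp1")
  expect_equal(nrow(pk), 1)
})

test_that("estimate_period demands at least three peaks", {
  t <- seq(0, 30, by = 0.01)
  pk <- detect_peaks(make_traj(t, cos(2 * pi * t / 24)), "Mp1")
  expect_lt(nrow(pk), 3)
  expect_error(estimate_period(pk), "arrhythmic|insufficient")
})

test_that("synthetic periodic peak times give exact period and zero dispersion", {
  pk <- structure(tibble::tibble(variable = "x",
                                 time = c(0, 24, 48, 72),
                                 height = 1),
                  class = c("peak_series", class(tibble::tibble())))
  est <- estimate_period(pk)
  expect_equal(est$period, 24)
  expect_equal(est$period_sd, 0)
})

test_that("rhythmicity classes: sustained, damped, flat", {
  t <- seq(0, 300, by = 0.05)
  sustained <- make_traj(t, 1 + cos(2 * pi * t / 24), transient = 50)
  expect_equal(classify_rhythmicity(sustained), "rhythmic")
  flat <- make_traj(t, c(cos(2 * pi * t[t < 20] / 24),
                         rep(0, sum(t >= 20))), transient = 50)
  expect_equal(classify_rhythmicity(flat), "arrhythmic")
  damped <- make_traj(t, exp(-0.008 * t) * cos(2 * pi * t / 24),
                      transient = 50)
  expect_equal(classify_rhythmicity(damped), "damped")
  short <- make_traj(seq(0, 60, 0.05), cos(seq(0, 60, 0.05)),
                     transient = 0)
  expect_error(classify_rhythmicity(short), "5 nominal cycles")
})

test_that("normalize01 maps to [0,1], is idempotent, errors on constants", {
  tr <- make_traj(c(0, 1, 2), c(2, 4, 6))
  n1 <- normalize01(tr, "Mp1")
  expect_equal(n1$value, c(0, 0.5, 1))
  tr2 <- make_traj(c(0, 1, 2), c(0, 0.5, 1))
  expect_equal(normalize01(tr2, "Mp1")$value, c(0, 0.5, 1))
  expect_error(normalize01(make_traj(c(0, 1), c(1, 1)), "Mp1"), "constant")
})

test_that("circadian-time conversion anchors the reference peak and scales by the period", {
  pc <- phase_convention("CT", ref_time = 100, ref_ct = 6, period = 23.75)
  expect_equal(to_circadian_time(100, pc), 6)
  expect_equal(to_circadian_time(100 + 23.75, pc), 6)
  expect_equal(to_circadian_time(100 + 23.75 / 2, pc), 18)
  # per1-mutant style anchor: per2 mRNA peak assigned CT 8
  pc8 <- phase_convention("CT", ref_time = 0, ref_ct = 8, period = 24)
  expect_equal(to_circadian_time(3, pc8), 11)
  expect_error(phase_convention("CT", ref_time = 0, period = -1), "period")
})

test_that("internal and external time follow the Daan-Merrow conventions", {
  expect_equal(to_internal_time(18), 0)
  expect_equal(to_internal_time(6), 12)
  ld1212 <- phase_convention("ZT", light_h = 12, dark_h = 12)
  expect_equal(to_external_time(0, ld1212), 6)
  expect_equal(to_external_time(6, ld1212), 12)  # mid-light is ExT 12
  ld618 <- phase_convention("ZT", light_h = 6, dark_h = 18)
  expect_equal(to_external_time(18, ld618), 3)
  expect_equal(to_external_time(3, ld618), 12)   # mid-light again
})

test_that("simulate_clock stays at a fixed point from an exact equilibrium", {
  # with Bmal1 transcription silenced the origin is an equilibrium
  p <- clock_params(vs3 = 0, vs4 = 0)
  traj <- simulate_clock(p, light_dd(), t_end = 130, transient = 0,
                         init = clock_state(default = 0), dt = 0.1)
  expect_lt(max(abs(as.matrix(traj[, -1]))), 1e-8)
})
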