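# Light protocols and the per-gene gating of photic input.

test_that("light protocols evaluate piecewise with half-open boundaries", {
  expect_equal(light_at(light_dd(), c(-5, 0, 100)), c(0, 0, 0))
  lp <- light_ld(12, 12, L_on = 0.1)
  expect_equal(light_at(lp, c(0, 6, 11.999)), c(0.1, 0.1, 0.1))
  expect_equal(light_at(lp, c(12, 18, 23.999)), c(0, 0, 0))
  expect_equal(light_at(lp, 24 + 6), 0.1)   # periodic
  # short photoperiod
  lp6 <- light_ld(6, 18, L_on = 0.1)
  expect_equal(light_at(lp6, c(3, 9)), c(0.1, 0))
  # pulse overlay: amplitude replaces baseline inside [start, start+dur)
  pp <- light_pulse(light_dd(), start = 14, duration = 0.5, amplitude = 0.2)
  expect_equal(light_at(pp, c(13.9, 14, 14.25, 14.5)), c(0, 0.2, 0.2, 0))
  expect_error(light_pulse(light_dd(), start = 1, duration = -1,
                           amplitude = 1), "duration")
  expect_error(light_ld(12, 13), "cycle")
  expect_error(light_constant(-0.1), "L")
})

test_that("per1 gate is constant at Lmax/2", {
  g <- gating_spec("per_gene")
  expect_equal(gate_per1(c(0, 17.3, 100), g), c(0.5, 0.5, 0.5))
  g2 <- gating_spec("per_gene", Lmax = 2)
  expect_equal(gate_per1(5, g2), 1.0)
})

test_that("per2 gate follows the piecewise-linear cycle", {
  g <- gating_spec("per_gene", Lmax = 1, tau = 24)
  y1 <- 1.3 * 3.5 / 24
  y2 <- 1.3 * 15 / 24
  expect_equal(gate_per2(0, g), y1)
  expect_equal(gate_per2(3.5, g), y1, tolerance = 1e-12)
  expect_equal(gate_per2(10, g), 1.3 * 10 / 24)
  expect_equal(gate_per2(16, g), y2)         # high plateau
  expect_equal(gate_per2(20, g), y2)
  # linear return and continuity across the cycle boundary
  expect_equal(gate_per2(24, g), y1)
  expect_equal(gate_per2(24 + 1e-9, g), y1, tolerance = 1e-6)
  # maximum attained on the high plateau (covers CT 15-20 for tau = 24)
  u <- seq(0, 24, by = 0.01)
  v <- gate_per2(u, g)
  expect_equal(max(v), y2)
  expect_true(all(u[v == max(v)] >= 15 & u[v == max(v)] <= 22))
  # bounds from the definition
  expect_true(all(v >= 0 & v <= 1.3 * 15 / 24 + 1e-12))
})

test_that("gating validation rejects disordered breakpoints", {
  expect_error(gating_spec("per_gene", t1 = 10, t2 = 5), "breakpoints")
  expect_error(gating_spec("custom"), "fn")
})

test_that("effective light multiplies gate and protocol", {
  g <- gating_spec("per_gene")
  pulse <- light_pulse(light_dd(), start = 14, duration = 1, amplitude = 1)
  # per1: unit pulse scaled to half
  expect_equal(effective_light(pulse, g, "per1", 14.1), 0.5)
  # per2: gate value at that phase
  expect_equal(effective_light(pulse, g, "per2", 14.1),
               gate_per2(14.1, g))
  # darkness stays dark whatever the gate does
  expect_equal(effective_light(light_dd(), g, "per2", seq(0, 48, 3)),
               rep(0, 17))
  # gating off reduces to the raw protocol
  expect_equal(effective_light(pulse, gating_none(), "per1", 14.1), 1)
})

test_that("gating phase origin shifts the per2 gate cycle", {
  g0 <- gating_spec("per_gene", origin = 0)
  g6 <- gating_spec("per_gene", origin = 6)
  expect_equal(gate_per2(16, g6), gate_per2(10, g0))
})
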