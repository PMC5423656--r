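# Steady states, eigenvalue classification and parameter scans.

test_that("steady-state residual vanishes against the independent oracle", {
  p <- clock_params()
  ss <- find_steady_state(p, L = 0)
  res <- oracle_rhs(ss, p, L1 = 0, L2 = 0)
  expect_lt(max(abs(res)), 1e-9)
})

test_that("origin is the exact steady state when Bmal1 transcription is off", {
  p <- clock_params(vs3 = 0, vs4 = 0)
  ss <- find_steady_state(p, L = 0, start = clock_state(default = 0.01))
  expect_lt(max(ss), 1e-8)
})

test_that("decoupled linear test system has analytic eigenvalues", {
  # zero all couplings and Michaelis terms: every species decays at kd_i
  p <- clock_params(set = "zero")
  kds <- seq(0.1, 1.3, by = 0.1)
  ov <- as.list(setNames(kds, paste0("kd", 1:13)))
  p <- apply_mutant(p, overrides = ov)
  ev <- jacobian_eigenvalues(p, clock_state(default = 0.5), L = 0)
  expect_equal(sort(Re(ev)), sort(-kds), tolerance = 1e-5)
  expect_true(all(abs(Im(ev)) < 1e-8))
})

test_that("light scan classifies by eigenvalue, brackets one Hopf point, and agrees with simulation", {
  p <- clock_params()
  grid <- seq(0, 0.6, length.out = 13)
  sc <- scan_parameter(p, "L", grid, sim_t_end = 600, sim_transient = 350)
  expect_true(sc$class[1] == "oscillatory")        # DD oscillates
  expect_true(sc$class[nrow(sc)] == "stable")      # strong light damps
  hopf <- attr(sc, "hopf")
  expect_equal(nrow(hopf), 1)
  # eigenvalue classification agrees with long-time simulation away from
  # the immediate Hopf neighborhood (finite-time decay there is too slow
  # to distinguish from a sustained rhythm)
  near_hopf <- is.na(sc$class) |
    (sc$value >= hopf[1, "lower"] & sc$value <= hopf[1, "upper"])
  for (i in which(!near_hopf)) {
    traj <- simulate_clock(p, light_ll(sc$value[i]), t_end = 700,
                           transient = 400, dt = 0.05)
    cls <- classify_rhythmicity(traj)
    if (sc$class[i] == "oscillatory") expect_equal(cls, "rhythmic")
    else expect_true(cls %in% c("arrhythmic", "damped"))
  }
  # supercritical signature: on a refined grid around the bracket the
  # limit-cycle amplitude decreases continuously toward the Hopf point
  fine <- scan_parameter(p, "L",
                         seq(max(0, hopf[1, "lower"] - 0.03),
                             hopf[1, "upper"], length.out = 6),
                         sim_t_end = 900, sim_transient = 600)
  osc <- fine[!is.na(fine$class) & fine$class == "oscillatory", ]
  expect_gte(nrow(osc), 2)
  expect_lt(osc$amplitude[nrow(osc)], osc$amplitude[1])
})

test_that("period sensitivity: null perturbation scores zero, per1 parameters are dead in the per1 mutant", {
  p <- clock_params()
  ps <- period_sensitivity(p, delta = 0, subset = c("vs2", "v5"))
  expect_equal(ps$sensitivity, c(0, 0), tolerance = 1e-4)
  # per1 mutant: parameters feeding only the per1 limb cannot move the period
  p1 <- apply_mutant(p, "per1")
  ps1 <- period_sensitivity(p1, delta = 0.05, ref = "Mp2",
                            subset = c("v1", "ke1", "kd1", "k1", "v2"))
  expect_true(all(abs(ps1$sensitivity) < 5e-3))
})
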