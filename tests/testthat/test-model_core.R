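# Core data model and right-hand side of the 13-variable network.

test_that("rhs agrees with an independent term-by-term oracle on random states", {
  p <- clock_params()
  states <- random_states(1000)
  worst <- 0
  for (st in states) {
    a <- clock_rhs(st, 0, p, light_per1 = 0.05, light_per2 = 0.03)
    b <- oracle_rhs(st, p, L1 = 0.05, L2 = 0.03)
    rel <- abs(a - b) / pmax(abs(b), 1e-8)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-12)
})

test_that("zero state: only Bmal1 transcription and light act; vs3 = 0 gives a fixed point", {
  p <- clock_params()
  z <- clock_state(default = 0)
  d <- clock_rhs(z, 0, p, 0)
  # with no repressor present the Bmal1 promoter is fully derepressed,
  # so dMB/dt = vs3; every other production term is a Hill function of zero
  expect_equal(unname(d[["MB"]]), unname(p[["vs3"]]))
  expect_equal(unname(d[setdiff(names(d), "MB")]),
               rep(0, 12))
  # light enters additively in the two per transcript equations only
  dl <- clock_rhs(z, 0, p, 0.1)
  expect_equal(unname(dl[["Mp1"]]), 0.1)
  expect_equal(unname(dl[["Mp2"]]), 0.1)
  expect_equal(dl[setdiff(names(dl), c("Mp1", "Mp2"))],
               d[setdiff(names(d), c("Mp1", "Mp2"))])
  # silencing Bmal1 transcription makes the origin a true fixed point
  p0 <- clock_params(vs3 = 0)
  expect_equal(max(abs(clock_rhs(z, 0, p0, 0))), 0)
})

test_that("rhs rejects non-finite states and negative light", {
  p <- clock_params()
  st <- clock_state()
  st[["BN"]] <- NaN
  expect_error(clock_rhs(st, 0, p), "BN")
  expect_error(clock_rhs(clock_state(), 0, p, light_per1 = -0.1), "light")
})

test_that("nonnegative orthant is forward-invariant at sampled boundary states", {
  p <- clock_params()   # calibrated set has kk = 0
  set.seed(7)
  for (rep in 1:200) {
    st <- clock_state_names()
    s <- stats::setNames(stats::runif(13, 0, 3), st)
    zero_at <- sample(st, sample(1:3, 1))
    s[zero_at] <- 0
    d <- clock_rhs(s, 0, p, stats::runif(1, 0, 0.2))
    expect_true(all(d[zero_at] >= 0),
                info = paste("negative derivative at zero boundary:",
                             paste(zero_at, collapse = ",")))
  }
})

test_that("nuclear PER1 removal of nuclear PER2 (kk) is the one printed exception to invariance", {
  p <- clock_params(kk = 0.2)
  s <- clock_state(P2n = 0, P1n = 1)
  d <- clock_rhs(s, 0, p, 0)
  expect_lt(d[["P2n"]], 0)   # the -kk*P1n term acts even at P2n = 0
})

test_that("zeroing kp1, kp2, kd12 decouples the PER1-BMAL1 complex", {
  p <- clock_params(kp1 = 0, kp2 = 0, kd12 = 0)
  set.seed(11)
  for (i in 1:20) {
    s <- stats::setNames(stats::runif(13, 0, 2), clock_state_names())
    s[["PB1"]] <- 0
    expect_identical(unname(clock_rhs(s, 0, p, 0)[["PB1"]]), 0)
  }
})

test_that("mutant presets reproduce the published override sets exactly", {
  p <- clock_params()
  p1 <- apply_mutant(p, "per1")
  expect_equal(unname(p1[c("vs1", "v4", "kp4")]), c(0, 0.43, 0.19))
  expect_equal(p1[setdiff(names(p), c("vs1", "v4", "kp4"))],
               p[setdiff(names(p), c("vs1", "v4", "kp4"))])

  p2 <- apply_mutant(p, "per2_ldc")
  expect_equal(unname(p2[c("vs1", "vs2", "vs3", "vs5")]),
               c(0.7, 0, 4.5, 0.5))
  expect_equal(unname(p2[c("v1", "v2", "v3", "k1", "kd3", "kp1", "kp2")]),
               c(0.44, 1.38, 1.67, 1.44, 0.08, 0.11, 0.18))

  expect_equal(unname(apply_mutant(p, "per2_Brdm1")[["vs2"]]), 0)
  dbl <- apply_mutant(p, "per1_per2")
  expect_equal(unname(dbl[c("vs1", "vs2")]), c(0, 0))
  expect_equal(unname(apply_mutant(p, "bmal1")[c("vs3", "vs4")]), c(0, 0))
  expect_equal(unname(apply_mutant(p, "rev_erba")[["vs5"]]), 0)

  # identity and error paths
  expect_identical(apply_mutant(p, "wild_type"), p)
  expect_error(apply_mutant(p, "nonsense"), "genotype")
  expect_error(apply_mutant(p, overrides = list(zz9 = 1)), "zz9")
})

test_that("parameter files round-trip in both formats and reject unknown keys", {
  p <- clock_params(vs1 = 0.123456789012345)
  kv <- tempfile(fileext = ".txt")
  tab <- tempfile(fileext = ".csv")
  write_clock_params(p, kv, format = "keyvalue")
  write_clock_params(p, tab, format = "table")
  expect_equal(as.numeric(read_clock_params(kv)), as.numeric(p),
               tolerance = 0)
  expect_equal(as.numeric(read_clock_params(tab)), as.numeric(p),
               tolerance = 0)
  bad <- tempfile()
  writeLines(c("vs1 = 1", "bogus = 2"), bad)
  expect_error(read_clock_params(bad), "bogus")
})

test_that("parameter validation enforces nonnegativity and Hill floors", {
  expect_error(clock_params(vs1 = -1), "vs1")
  expect_error(clock_params(m = 0.5), "Hill")
  expect_error(clock_params(nonsense = 1), "nonsense")
})
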