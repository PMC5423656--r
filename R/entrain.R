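# Entrainment to light-dark cycles, photoperiod sweeps and constant-light
# period curves.

#' Entrain the clock to a light-dark cycle
#'
#' Simulates the model under a 24 h square-wave light-dark cycle until the
#' oscillation locks to the zeitgeber, then reports peak phases in external
#' time (ExT). Locking is declared when successive reference-variable peaks
#' are spaced 24 +/- `lock_tol` h apart over at least `lock_cycles`
#' consecutive cycles of the assessment window. The reference variable is
#' the genotype's phase marker (per1 mRNA for wild type, per2 mRNA for the
#' per1 mutant, cytosolic PER1 for per2 mutants). A photoperiod of 0 light
#' hours is free run: phases are then reported in circadian time instead.
#'
#' @param params Base parameter set.
#' @param genotype Genotype label.
#' @param light_h Light-phase duration (h, in a 24 h cycle).
#' @param L_on Light intensity during the light phase (default 0.1).
#' @param gating A [gating_spec()]; under entrainment the gate cycle runs at
#'   the 24 h zeitgeber period, anchored at lights-on.
#' @param n_cycles Total cycles simulated (default 60).
#' @param discard Cycles discarded as transient (default 40).
#' @param lock_tol,lock_cycles Locking criterion (see above).
#' @param init Initial state.
#' @param dt,rtol,atol Solver settings.
#' @return An `entrainment_summary` tibble: one row per tracked variable
#'   with columns `genotype`, `light_h`, `dark_h`, `gated`, `entrained`,
#'   `variable`, `phase` (ExT under LD, CT under DD), plus attributes. The
#'   per1-per2 mRNA peak-phase difference is in attribute
#'   `per1_per2_diff_h` and in [glance()].
#' @export
entrain <- function(params, genotype = "wild_type", light_h, L_on = 0.1,
                    gating = gating_none(), n_cycles = 60, discard = 40,
                    lock_tol = 0.05, lock_cycles = 5,
                    init = clock_state(), dt = 0.01,
                    rtol = 1e-8, atol = 1e-10) {
  if (light_h < 0 || light_h > 24)
    stop("light_h must be in [0, 24]", call. = FALSE)
  p <- apply_mutant(params, genotype)
  ref <- .reference_marker(genotype)
  dark_h <- 24 - light_h
  gated <- gating$mode != "none"

  if (light_h == 0) {
    # free run: report CT phases
    traj <- simulate_clock(p, light_dd(), gating_none(),
                           t_end = n_cycles * 24, transient = discard * 24,
                           init = init, dt = dt, rtol = rtol, atol = atol,
                           genotype = genotype)
    pk_ref <- detect_peaks(traj, ref$var)
    if (nrow(pk_ref) < 3)
      return(.entrain_result(genotype, light_h, dark_h, gated,
                             FALSE, NULL, NA))
    per <- estimate_period(pk_ref)$period
    conv <- phase_convention("CT", ref_time = pk_ref$time[1],
                             ref_ct = ref$ct, period = per)
    phases <- vapply(.state_names, function(v) {
      pk <- detect_peaks(traj, v)
      if (nrow(pk) < 3) return(NA_real_)
      mean(to_circadian_time(pk$time, conv))
    }, 0)
    diff12 <- .circ_diff(phases[["Mp1"]], phases[["Mp2"]])
    return(.entrain_result(genotype, light_h, dark_h, gated, TRUE,
                           phases, diff12, period = per, scale = "CT"))
  }

  gspec <- gating
  if (gating$mode == "per_gene")
    gspec <- gating_spec("per_gene", Lmax = gating$Lmax, tau = 24,
                         origin = gating$origin)
  protocol <- light_ld(light_h, dark_h, L_on = L_on)
  traj <- simulate_clock(p, protocol, gspec, t_end = n_cycles * 24,
                         transient = discard * 24, init = init, dt = dt,
                         rtol = rtol, atol = atol, genotype = genotype)
  pk_ref <- detect_peaks(traj, ref$var)
  iv <- diff(pk_ref$time)
  locked <- length(iv) >= lock_cycles &&
    all(abs(utils::tail(iv, lock_cycles) - 24) <= lock_tol)
  if (!locked)
    return(.entrain_result(genotype, light_h, dark_h, gated, FALSE,
                           NULL, NA))
  conv <- phase_convention("ZT", lights_on = 0, light_h = light_h,
                           dark_h = dark_h)
  phases <- vapply(.state_names, function(v) {
    pk <- detect_peaks(traj, v)
    if (nrow(pk) < lock_cycles) return(NA_real_)
    zts <- to_zeitgeber_time(pk$time, conv)
    ext <- to_external_time(zts, conv)
    .circ_mean(ext)
  }, 0)
  diff12 <- .circ_diff(phases[["Mp1"]], phases[["Mp2"]])
  .entrain_result(genotype, light_h, dark_h, gated, TRUE, phases, diff12,
                  scale = "ExT")
}

.circ_mean <- function(x, mod = 24) {
  ang <- x / mod * 2 * pi
  (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * mod) %% mod
}

# absolute circular difference in hours, in [0, 12]
.circ_diff <- function(a, b, mod = 24) {
  d <- abs(a - b) %% mod
  min(d, mod - d)
}

.entrain_result <- function(genotype, light_h, dark_h, gated, entrained,
                            phases, diff12, period = NA, scale = "ExT") {
  tb <- if (is.null(phases)) {
    tibble(genotype = genotype, light_h = light_h, dark_h = dark_h,
           gated = gated, entrained = entrained,
           variable = character(0) , phase = numeric(0))[0, ]
  } else {
    tibble(genotype = genotype, light_h = light_h, dark_h = dark_h,
           gated = gated, entrained = entrained,
           variable = names(phases), phase = unname(phases))
  }
  structure(tb, class = c("entrainment_summary", class(tibble())),
            per1_per2_diff_h = diff12, period = period,
            phase_scale = scale, entrained = entrained)
}

#' Sweep peak phases across photoperiods
#'
#' Runs [entrain()] for a list of photoperiods and collects the per1/per2
#' mRNA (and PER1/PER2 protein) peak phases with the per1-per2 phase
#' difference per photoperiod.
#'
#' @inheritParams entrain
#' @param light_hours Vector of light-phase durations (h, each in [0, 24]).
#' @return A tibble with one row per photoperiod: `light_h`, `entrained`,
#'   `per1_ext`, `per2_ext`, `diff_h`, `PER1_ext`, `PER2_ext`, `scale`.
#' @export
photoperiod_sweep <- function(params, genotype = "wild_type", light_hours,
                              L_on = 0.1, gating = gating_none(), ...) {
  rows <- lapply(light_hours, function(lh) {
    es <- entrain(params, genotype, light_h = lh, L_on = L_on,
                  gating = gating, ...)
    ph <- function(v) {
      i <- which(es$variable == v)
      if (length(i)) es$phase[i] else NA_real_
    }
    tibble(genotype = genotype, light_h = lh,
           entrained = attr(es, "entrained"),
           per1_ext = ph("Mp1"), per2_ext = ph("Mp2"),
           diff_h = attr(es, "per1_per2_diff_h"),
           PER1_ext = ph("P1c"), PER2_ext = ph("P2c"),
           scale = attr(es, "phase_scale"),
           gated = gating$mode != "none")
  })
  dplyr::bind_rows(rows)
}

#' Free-running period as a function of constant-light intensity
#'
#' Simulates the model in constant light over a grid of intensities and
#' estimates the free-running period at each; intensities at which the
#' oscillation dies (beyond the Hopf point) are flagged rather than failed.
#' The dedicated constant-light parameter set (`clock_params(set =
#' "wt_ll")`) shows the classical intensity dependence; the darkness-
#' calibrated set only oscillates over a narrow intensity range with little
#' period change.
#'
#' @inheritParams entrain
#' @param L_values Vector of constant light intensities (each >= 0).
#' @param t_end,transient Simulation span and discard (h).
#' @return A tibble: `genotype`, `L`, `oscillatory`, `period`, `amplitude`
#'   (peak-to-trough of per1 mRNA).
#' @export
ll_period_curve <- function(params, genotype = "wild_type", L_values,
                            t_end = 1100, transient = 600,
                            init = clock_state(), dt = 0.01,
                            rtol = 1e-8, atol = 1e-10) {
  if (any(L_values < 0)) stop("L values must be >= 0", call. = FALSE)
  p <- apply_mutant(params, genotype)
  rows <- lapply(L_values, function(L) {
    traj <- simulate_clock(p, light_ll(L), t_end = t_end,
                           transient = transient, init = init, dt = dt,
                           rtol = rtol, atol = atol, genotype = genotype)
    pk <- detect_peaks(traj, "Mp1")
    amp <- {
      post <- traj[traj$time >= transient, ]
      diff(range(post$Mp1))
    }
    if (nrow(pk) >= 3 && classify_rhythmicity(traj) == "rhythmic") {
      per <- estimate_period(pk)
      tibble(genotype = genotype, L = L, oscillatory = TRUE,
             period = per$period, amplitude = amp)
    } else {
      tibble(genotype = genotype, L = L, oscillatory = FALSE,
             period = NA_real_, amplitude = amp)
    }
  })
  dplyr::bind_rows(rows)
}
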