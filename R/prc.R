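# Phase response curves: shift of the free-running oscillator caused by a
# single light pulse, as a function of the circadian time of the pulse.

# converged limit-cycle state and reference-peak anchor for a genotype under
# DD; reused across all pulses of a PRC
.dd_anchor <- function(params, genotype, settle = 600, span = 200,
                       dt = 0.01, rtol = 1e-8, atol = 1e-10) {
  traj <- simulate_clock(params, light_dd(), t_end = settle + span,
                         transient = settle, dt = dt, rtol = rtol,
                         atol = atol, genotype = genotype)
  ref <- .reference_marker(genotype)
  pk <- detect_peaks(traj, ref$var)
  if (nrow(pk) < 3)
    stop("genotype ", genotype, " is arrhythmic under DD; no phase reference",
         call. = FALSE)
  per <- estimate_period(pk)$period
  # state at the first post-transient reference peak: phase origin
  anchor_t <- pk$time[1]
  idx <- which.min(abs(traj$time - anchor_t))
  list(state = clock_state_from_row(traj[idx, ]), period = per,
       ref = ref, t0 = traj$time[idx])
}

clock_state_from_row <- function(row) {
  s <- as.numeric(row[1, .state_names])
  setNames(pmax(s, 0), .state_names)
}

#' Phase shift caused by a single light pulse
#'
#' Starting from a converged free-running (DD) cycle, applies one rectangular
#' light pulse at the requested circadian time and measures the asymptotic
#' phase shift: both the perturbed and the unperturbed system are run on,
#' and the genotype's reference-variable peak is compared ten cycles after
#' the pulse (by which time the perturbed orbit has relaxed back to the
#' limit cycle). Advances are positive, delays negative, and the shift is
#' reported in (-12, 12] hours.
#'
#' The circadian reference follows the genotype: wild type uses the per1
#' mRNA peak (CT 6), the per1 mutant the per2 mRNA peak (CT 8), and the per2
#' mutants the cytosolic PER1 peak (CT 12).
#'
#' @param params Base (wild-type) parameter set.
#' @param genotype Genotype label, see [clock_genotypes()].
#' @param ct Circadian time of pulse onset (h).
#' @param duration Pulse duration (h, default 0.5).
#' @param amplitude Pulse light amplitude (dimensionless).
#' @param gating A [gating_spec()]; when per-gene gating is active the gate
#'   runs at the genotype's free-running period with its cycle origin at
#'   CT 0.
#' @param n_cycles Cycles between pulse and phase read-out (default 10).
#' @param anchor Optional precomputed anchor (internal reuse).
#' @return Phase shift in hours, advance positive.
#' @export
phase_shift <- function(params, genotype = "wild_type", ct, duration = 0.5,
                        amplitude, gating = gating_none(), n_cycles = 10,
                        anchor = NULL) {
  if (duration <= 0) stop("pulse duration must be > 0", call. = FALSE)
  if (amplitude < 0) stop("pulse amplitude must be >= 0", call. = FALSE)
  p <- apply_mutant(params, genotype)
  if (is.null(anchor)) anchor <- .dd_anchor(p, genotype)
  per <- anchor$period
  # t = 0 is the reference peak, i.e. CT = ref$ct; pulse onset at requested CT
  dct <- (ct - anchor$ref$ct) %% 24
  t_pulse <- dct / 24 * per
  t_end <- t_pulse + (n_cycles + 2.5) * per
  gspec <- gating
  if (gating$mode == "per_gene") {
    # free-running gate: tau = genotype period, u = 0 at CT 0
    t1 <- 3.5 * per / 24
    gspec <- gating_spec("per_gene", Lmax = gating$Lmax, tau = per,
                         origin = -anchor$ref$ct / 24 * per)
  }
  pulse <- light_pulse(light_dd(), start = t_pulse, duration = duration,
                       amplitude = amplitude)
  base <- simulate_clock(p, light_dd(), gating_none(), t_end = t_end,
                         transient = 0, init = anchor$state,
                         genotype = genotype)
  pert <- simulate_clock(p, pulse, gspec, t_end = t_end, transient = 0,
                         init = anchor$state, genotype = genotype)
  pk_b <- detect_peaks(base, anchor$ref$var, transient = 0)
  pk_p <- detect_peaks(pert, anchor$ref$var, transient = 0)
  # reference peak n_cycles after pulse onset
  tb <- pk_b$time[pk_b$time > t_pulse]
  tp <- pk_p$time[pk_p$time > t_pulse]
  n <- min(length(tb), length(tp), n_cycles)
  if (n < 1) stop("no post-pulse peaks; cannot measure shift", call. = FALSE)
  raw <- tb[n] - tp[n]          # perturbed earlier => advance => positive
  shift <- ((raw / per * 24 + 12) %% 24) - 12
  if (shift <= -12) shift <- shift + 24
  shift
}

#' Compute a phase response curve
#'
#' Evaluates [phase_shift()] over a grid of circadian times with a common
#' pulse template, reusing one converged limit-cycle anchor per genotype.
#'
#' @inheritParams phase_shift
#' @param ct_grid Circadian times of pulse onset (default hourly, 0..23).
#' @return A `prc_result` tibble: columns `ct`, `shift_h`, `genotype`,
#'   `amplitude`, `duration`, `gated`.
#' @examples
#' \donttest{
#' prc <- compute_prc(clock_params(), "wild_type", amplitude = 0.35,
#'                    ct_grid = seq(0, 23, by = 2))
#' }
#' @export
compute_prc <- function(params, genotype = "wild_type", amplitude,
                        duration = 0.5, gating = gating_none(),
                        ct_grid = 0:23, n_cycles = 10) {
  if (any(ct_grid < 0 | ct_grid >= 24))
    stop("ct_grid must lie in [0, 24)", call. = FALSE)
  p <- apply_mutant(params, genotype)
  anchor <- .dd_anchor(p, genotype)
  shifts <- vapply(ct_grid, function(ct)
    phase_shift(params, genotype, ct, duration, amplitude, gating,
                n_cycles, anchor = anchor), 0)
  structure(
    tibble(ct = ct_grid, shift_h = shifts, genotype = genotype,
           amplitude = amplitude, duration = duration,
           gated = gating$mode != "none"),
    class = c("prc_result", class(tibble())),
    period = anchor$period)
}
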