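#' Light protocols
#'
#' Constructors for the light regimes used throughout the package, all
#' evaluated through [light_at()]:
#' * `light_constant(L)` — constant light of intensity `L`; `light_dd()` is
#'   `light_constant(0)` (constant darkness) and `light_ll(L)` constant
#'   light.
#' * `light_ld(light_h, dark_h, L_on)` — square-wave light-dark cycle with
#'   lights-on at t = 0 (ZT 0); the value is `L_on` on the half-open light
#'   phase `[0, light_h)` of each cycle and 0 in the dark phase.
#' * `light_pulse(base, start, duration, amplitude)` — overlays a single
#'   rectangular pulse of the given amplitude on `base` over
#'   `[start, start + duration)`; during the pulse the pulse amplitude
#'   replaces the baseline.
#'
#' @param L,L_on Dimensionless light intensity (>= 0).
#' @param light_h,dark_h Durations of light and dark phase in hours; they
#'   must sum to the cycle length.
#' @param cycle Cycle length in hours (default 24).
#' @param base A light protocol to overlay the pulse on.
#' @param start,duration,amplitude Pulse onset time (h), duration (h, > 0)
#'   and amplitude.
#' @return An object of class `light_protocol`.
#' @examples
#' lp <- light_ld(12, 12, L_on = 0.1)
#' light_at(lp, c(6, 18))   # 0.1, 0
#' @export
light_constant <- function(L = 0) {
  if (!is.finite(L) || L < 0) stop("L must be finite and >= 0", call. = FALSE)
  structure(list(kind = "constant", L = L), class = "light_protocol")
}

#' @rdname light_constant
#' @export
light_dd <- function() light_constant(0)

#' @rdname light_constant
#' @export
light_ll <- function(L) light_constant(L)

#' @rdname light_constant
#' @export
light_ld <- function(light_h, dark_h = NULL, L_on = 0.1, cycle = 24) {
  if (is.null(dark_h)) dark_h <- cycle - light_h
  if (light_h < 0 || dark_h < 0)
    stop("light and dark durations must be >= 0", call. = FALSE)
  if (abs(light_h + dark_h - cycle) > 1e-9)
    stop("light_h + dark_h must equal the cycle length", call. = FALSE)
  if (!is.finite(L_on) || L_on < 0)
    stop("L_on must be finite and >= 0", call. = FALSE)
  structure(list(kind = "square_wave", L = L_on, cycle = cycle,
                 light_h = light_h, dark_h = dark_h),
            class = "light_protocol")
}

#' @rdname light_constant
#' @export
light_pulse <- function(base = light_dd(), start, duration = 0.5,
                        amplitude) {
  stopifnot(inherits(base, "light_protocol"))
  if (!is.finite(duration) || duration <= 0)
    stop("pulse duration must be > 0", call. = FALSE)
  if (!is.finite(amplitude) || amplitude < 0)
    stop("pulse amplitude must be >= 0", call. = FALSE)
  structure(list(kind = "pulse_overlay", base = base, start = start,
                 duration = duration, amplitude = amplitude),
            class = "light_protocol")
}

#' Evaluate a light protocol
#'
#' @param protocol A `light_protocol`.
#' @param t Time(s) in hours.
#' @return Numeric vector of light values (dimensionless, >= 0).
#' @export
light_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "light_protocol"))
  if (anyNA(t) || any(!is.finite(t))) stop("t must be finite", call. = FALSE)
  switch(protocol$kind,
    constant = rep(protocol$L, length(t)),
    square_wave = {
      u <- t %% protocol$cycle
      ifelse(u < protocol$light_h, protocol$L, 0)
    },
    pulse_overlay = {
      inside <- t >= protocol$start & t < protocol$start + protocol$duration
      ifelse(inside, protocol$amplitude, light_at(protocol$base, t))
    }
  )
}

# times in (t_from, t_to) at which the raw light level switches; the
# integrator restarts at each of these
.light_breaks <- function(protocol, t_from, t_to) {
  switch(protocol$kind,
    constant = numeric(0),
    square_wave = {
      cyc <- protocol$cycle
      k <- seq(floor(t_from / cyc) - 1, ceiling(t_to / cyc) + 1)
      br <- sort(c(k * cyc, k * cyc + protocol$light_h))
      br[br > t_from & br < t_to]
    },
    pulse_overlay = {
      br <- c(.light_breaks(protocol$base, t_from, t_to),
              protocol$start, protocol$start + protocol$duration)
      sort(unique(br[br > t_from & br < t_to]))
    }
  )
}

# ---------------------------------------------------------------------------
# Gating

#' Per-gene gating of the light input
#'
#' Gating scales the light input to per1 and per2 in a phase-dependent way.
#' The per1 gate is constant at `Lmax/2`; the per2 gate is a piecewise-linear
#' cycle over the reference period `tau`: a low plateau `y1` up to `t1`, a
#' linear rise `Lmax * 1.3 * u / tau` to `t2`, a high plateau `y2` through
#' `t3` (covering roughly CT 15-20 for `tau = 24`, where the phase-response
#' delay region is deepest), then linear return to `y1` at `t4 = tau`.
#' Under free run `tau` is the genotype's endogenous period; under entrainment
#' it is the 24 h zeitgeber period. `origin` sets the time at which the gating
#' cycle phase u is 0 (CT 0 of the reference oscillation).
#'
#' @param mode `"none"`, `"per_gene"` (the piecewise form above) or
#'   `"custom"` (supply `fn(t, gene)` returning a multiplier).
#' @param Lmax Gate ceiling scale (default 1).
#' @param tau Reference period in hours.
#' @param t1,t2,t3,t4,y1,y2 Breakpoints (h) and plateau values; defaults
#'   `t1 = 3.5 tau/24`, `t2 = 15 tau/24`, `t3 = 22 tau/24`, `t4 = tau`,
#'   `y1 = 1.3 Lmax t1/tau`, `y2 = 1.3 Lmax t2/tau`.
#' @param origin Time (h) mapped to gating phase u = 0.
#' @param fn Custom gating function for `mode = "custom"`.
#' @return An object of class `gating_spec`.
#' @export
gating_spec <- function(mode = c("none", "per_gene", "custom"), Lmax = 1,
                        tau = 24, t1 = 3.5 * tau / 24, t2 = 15 * tau / 24,
                        t3 = 22 * tau / 24, t4 = tau,
                        y1 = Lmax * 1.3 * t1 / tau,
                        y2 = Lmax * 1.3 * t2 / tau,
                        origin = 0, fn = NULL) {
  mode <- match.arg(mode)
  if (mode != "none") {
    if (!(0 < t1 && t1 < t2 && t2 < t3 && t3 < t4))
      stop("gating breakpoints must satisfy 0 < t1 < t2 < t3 < t4",
           call. = FALSE)
    if (abs(t4 - tau) > 1e-9)
      stop("t4 must equal the reference period tau", call. = FALSE)
  }
  if (mode == "custom" && !is.function(fn))
    stop("custom gating needs a function fn(t, gene)", call. = FALSE)
  structure(list(mode = mode, Lmax = Lmax, tau = tau, t1 = t1, t2 = t2,
                 t3 = t3, t4 = t4, y1 = y1, y2 = y2, origin = origin,
                 fn = fn),
            class = "gating_spec")
}

#' @rdname gating_spec
#' @export
gating_none <- function() gating_spec("none")

#' Gating multipliers and gated light
#'
#' `gate_per1()` and `gate_per2()` evaluate the per-gene gating multipliers
#' at time `t`; `effective_light()` combines them with a light protocol and
#' returns the light input actually applied to the given gene's mRNA
#' equation.
#'
#' @param t Time(s), hours.
#' @param spec A [gating_spec()].
#' @param protocol A `light_protocol`.
#' @param gene `"per1"` or `"per2"`.
#' @return Numeric vector.
#' @examples
#' gate_per1(0, gating_spec("per_gene"))   # 0.5
#' @export
gate_per1 <- function(t, spec) {
  stopifnot(inherits(spec, "gating_spec"))
  switch(spec$mode,
    none = rep(1, length(t)),
    per_gene = rep(spec$Lmax / 2, length(t)),
    custom = spec$fn(t, "per1")
  )
}

#' @rdname gate_per1
#' @export
gate_per2 <- function(t, spec) {
  stopifnot(inherits(spec, "gating_spec"))
  if (spec$mode == "none") return(rep(1, length(t)))
  if (spec$mode == "custom") return(spec$fn(t, "per2"))
  u <- (t - spec$origin) %% spec$tau
  vapply(u, function(ui) {
    if (ui <= spec$t1) spec$y1
    else if (ui <= spec$t2) spec$Lmax * 1.3 * ui / spec$tau
    else if (ui <= spec$t3) spec$y2
    else if (ui <= spec$t4)
      (spec$y1 - spec$y2) * (ui - spec$t3) / (spec$t4 - spec$t3) + spec$y2
    else spec$y1
  }, 0)
}

#' @rdname gate_per1
#' @export
effective_light <- function(protocol, spec, gene = c("per1", "per2"), t) {
  gene <- match.arg(gene)
  L <- light_at(protocol, t)
  g <- if (gene == "per1") gate_per1(t, spec) else gate_per2(t, spec)
  g * L
}
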