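#' Right-hand side of the single-cell clock model
#'
#' Evaluates the 13 coupled rate equations of the dual-oscillator gene
#' regulatory network: BMAL1-activated transcription of per1, per2 and
#' Rev-erba (Hill kinetics), REV-ERBa repression plus PER2 coactivation of
#' Bmal1, Michaelis-Menten enzymatic degradation and first-order decay of
#' every species, cytosol-to-nucleus transport, and reversible PER1-BMAL1 /
#' PER2-BMAL1 complex formation. Light enters additively in the per1 and
#' per2 mRNA equations; `light_per1` and `light_per2` are the (possibly
#' gated) light inputs for the two genes and normally coincide.
#'
#' @param state Named 13-vector, see [clock_state()].
#' @param t Time in hours (the autonomous equations ignore it; kept for the
#'   standard ODE signature).
#' @param params A [clock_params()] vector.
#' @param light_per1,light_per2 Dimensionless light inputs (>= 0) added to
#'   dMp1/dt and dMp2/dt. `light_per2` defaults to `light_per1`.
#' @return Named 13-vector of time derivatives (nM/h).
#' @export
clock_rhs <- function(state, t = 0, params, light_per1 = 0,
                      light_per2 = light_per1) {
  if (anyNA(state) || any(!is.finite(state))) {
    bad <- .state_names[!is.finite(state[.state_names])]
    stop("non-finite state component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.finite(light_per1) || light_per1 < 0 ||
      !is.finite(light_per2) || light_per2 < 0)
    stop("light inputs must be finite and >= 0", call. = FALSE)
  p <- validate_clock_params(params)
  s <- state[.state_names]

  hill <- function(x, K, n) if (x <= 0) 0 else x^n / (K^n + x^n)

  Mp1 <- s[["Mp1"]]; Mp2 <- s[["Mp2"]]
  P1c <- s[["P1c"]]; P1n <- s[["P1n"]]
  P2c <- s[["P2c"]]; P2n <- s[["P2n"]]
  MB <- s[["MB"]]; Bc <- s[["Bc"]]; BN <- s[["BN"]]
  MR <- s[["MR"]]; R <- s[["R"]]; PB1 <- s[["PB1"]]; PB2 <- s[["PB2"]]
  m <- p[["m"]]; w <- p[["w"]]; sx <- p[["s"]]

  d <- c(
    Mp1 = p[["vs1"]] * hill(BN, p[["ka1"]], m) -
      p[["v1"]] * Mp1 / (p[["ke1"]] + Mp1) - p[["kd1"]] * Mp1 + light_per1,
    Mp2 = p[["vs2"]] * hill(BN, p[["ka2"]], m) -
      p[["v4"]] * Mp2 / (p[["ke4"]] + Mp2) - p[["kd4"]] * Mp2 + light_per2,
    P1c = p[["k1"]] * Mp1 - p[["v2"]] * P1c / (p[["ke2"]] + P1c) -
      p[["kd2"]] * P1c,
    P1n = p[["k2"]] * P1c - p[["v3"]] * P1n / (p[["ke3"]] + P1n) +
      p[["kp1"]] * PB1 - p[["kp2"]] * P1n * BN - p[["kd3"]] * P1n,
    P2c = p[["k3"]] * Mp2 - p[["v5"]] * P2c / (p[["ke5"]] + P2c) -
      p[["kd5"]] * P2c,
    P2n = p[["k4"]] * P2c - p[["v6"]] * P2n / (p[["ke6"]] + P2n) +
      p[["kp3"]] * PB2 - p[["kp4"]] * P2n * BN - p[["kk"]] * P1n -
      p[["kd6"]] * P2n,
    MB = p[["vs3"]] * p[["kI1"]]^2 /
      (p[["kI1"]]^2 + R^2 + R * p[["kx"]]) +
      p[["vs4"]] * hill(P2n, p[["ka3"]], w) -
      p[["v7"]] * MB / (p[["ke7"]] + MB) - p[["kd7"]] * MB,
    Bc = p[["k5"]] * MB - p[["v8"]] * Bc / (p[["ke8"]] + Bc) -
      p[["kd8"]] * Bc,
    BN = p[["k6"]] * Bc - p[["v9"]] * BN / (p[["ke9"]] + BN) +
      p[["kp1"]] * PB1 - p[["kp2"]] * P1n * BN +
      p[["kp3"]] * PB2 - p[["kp4"]] * P2n * BN - p[["kd9"]] * BN,
    MR = p[["vs5"]] * hill(BN, p[["ka4"]], sx) -
      p[["v10"]] * MR / (p[["ke10"]] + MR) - p[["kd10"]] * MR,
    R = p[["k7"]] * MR - p[["v11"]] * R / (p[["ke11"]] + R) -
      p[["kd11"]] * R,
    PB1 = -p[["kp1"]] * PB1 + p[["kp2"]] * P1n * BN - p[["kd12"]] * PB1,
    PB2 = -p[["kp3"]] * PB2 + p[["kp4"]] * P2n * BN - p[["kd13"]] * PB2
  )
  d
}

# Parameter vector handed to the compiled single-cell model: the 61 kinetic
# constants followed by the light/gating block (see src/clock_rhs.c).
.c_parms <- function(params, L_seg, gating = NULL) {
  g <- if (is.null(gating)) {
    c(0, 1, 24, 3.5, 15, 22, 24, 1.3 * 3.5 / 24, 1.3 * 15 / 24, 0)
  } else {
    c(1, gating$Lmax, gating$tau, gating$t1, gating$t2, gating$t3,
      gating$t4, gating$y1, gating$y2, gating$origin)
  }
  c(unname(params), L_seg, g)
}
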