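# Independent, literal transcription of the 13 rate equations, written
# term-by-term from scratch as a cross-check oracle for clock_rhs(). It
# shares no code with the package implementation (scalar arithmetic only,
# one equation per block).
oracle_rhs <- function(state, params, L1 = 0, L2 = L1) {
  g <- function(nm) unname(params[[nm]])
  x <- function(nm) unname(state[[nm]])
  Mp1 <- x("Mp1"); Mp2 <- x("Mp2")
  P1c <- x("P1c"); P1n <- x("P1n"); P2c <- x("P2c"); P2n <- x("P2n")
  MB <- x("MB"); Bc <- x("Bc"); BN <- x("BN")
  MR <- x("MR"); R <- x("R"); PB1 <- x("PB1"); PB2 <- x("PB2")
  m <- g("m"); w <- g("w"); s <- g("s")

  act <- function(conc, K, n) {
    if (conc <= 0) return(0)
    cn <- exp(n * log(conc))
    cn / (exp(n * log(K)) + cn)
  }

  dMp1 <- g("vs1") * act(BN, g("ka1"), m) -
    g("v1") * Mp1 / (g("ke1") + Mp1) - g("kd1") * Mp1 + L1

  dMp2 <- g("vs2") * act(BN, g("ka2"), m) -
    g("v4") * Mp2 / (g("ke4") + Mp2) - g("kd4") * Mp2 + L2

  dP1c <- g("k1") * Mp1 - g("v2") * P1c / (g("ke2") + P1c) -
    g("kd2") * P1c

  dP1n <- g("k2") * P1c - g("v3") * P1n / (g("ke3") + P1n) +
    g("kp1") * PB1 - g("kp2") * P1n * BN - g("kd3") * P1n

  dP2c <- g("k3") * Mp2 - g("v5") * P2c / (g("ke5") + P2c) -
    g("kd5") * P2c

  dP2n <- g("k4") * P2c - g("v6") * P2n / (g("ke6") + P2n) +
    g("kp3") * PB2 - g("kp4") * P2n * BN - g("kk") * P1n -
    g("kd6") * P2n

  repression <- g("vs3") * g("kI1")^2 /
    (g("kI1")^2 + R^2 + R * g("kx"))
  dMB <- repression + g("vs4") * act(P2n, g("ka3"), w) -
    g("v7") * MB / (g("ke7") + MB) - g("kd7") * MB

  dBc <- g("k5") * MB - g("v8") * Bc / (g("ke8") + Bc) - g("kd8") * Bc

  dBN <- g("k6") * Bc - g("v9") * BN / (g("ke9") + BN) +
    g("kp1") * PB1 - g("kp2") * P1n * BN +
    g("kp3") * PB2 - g("kp4") * P2n * BN - g("kd9") * BN

  dMR <- g("vs5") * act(BN, g("ka4"), s) -
    g("v10") * MR / (g("ke10") + MR) - g("kd10") * MR

  dR <- g("k7") * MR - g("v11") * R / (g("ke11") + R) - g("kd11") * R

  dPB1 <- g("kp2") * P1n * BN - g("kp1") * PB1 - g("kd12") * PB1

  dPB2 <- g("kp4") * P2n * BN - g("kp3") * PB2 - g("kd13") * PB2

  c(Mp1 = dMp1, Mp2 = dMp2, P1c = dP1c, P1n = dP1n, P2c = dP2c,
    P2n = dP2n, MB = dMB, Bc = dBc, BN = dBN, MR = dMR, R = dR,
    PB1 = dPB1, PB2 = dPB2)
}

# random positive states drawn reproducibly
random_states <- function(n, seed = 42, scale = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    stats::setNames(stats::runif(13, 0, scale), clock_state_names()))
}
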