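/* Compiled right-hand sides for the single-cell dual-oscillator clock model
 * and the two-cell (VL/DM) coupled model, in the deSolve compiled-model
 * interface (initmod/derivs).
 *
 * Parameter vector layout (single cell), 0-based:
 *   0..4    vs1..vs5
 *   5..15   v1..v11
 *   16..26  ke1..ke11
 *   27..39  kd1..kd13
 *   40..46  k1..k7
 *   47..50  kp1..kp4
 *   51..54  ka1..ka4
 *   55 kI1, 56 kx, 57 kk
 *   58 m, 59 w, 60 s
 * light block (the integrator runs piecewise over segments where the raw
 * light level is constant; gating remains time-dependent):
 *   61 Lseg  raw light level on this segment
 *   62 gating mode (0 none, 1 per-gene gating)
 *   63 Lmax, 64 tau, 65..68 t1..t4, 69 y1, 70 y2, 71 t0 (gating phase origin)
 *
 * State order: Mp1, Mp2, P1c, P1n, P2c, P2n, MB, Bc, BN, MR, R, PB1, PB2.
 */
#include <R.h>
#include <math.h>

#define NP_SINGLE 72
#define NP_COUPLED 134

static double p[NP_SINGLE];
static double cp[NP_COUPLED];

void clock_initmod(void (*odeparms)(int *, double *))
{
    int n = NP_SINGLE;
    odeparms(&n, p);
}

void me_initmod(void (*odeparms)(int *, double *))
{
    int n = NP_COUPLED;
    odeparms(&n, cp);
}

static double hill_act(double x, double K, double n)
{
    double xn, Kn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n);
    Kn = pow(K, n);
    return xn / (Kn + xn);
}

/* per2 gating variable (piecewise linear over one cycle of length tau) */
static double gate2(double u, const double *g)
{
    /* g: Lmax, tau, t1..t4, y1, y2 */
    double Lmax = g[0], tau = g[1];
    double t1 = g[2], t2 = g[3], t3 = g[4], t4 = g[5];
    double y1 = g[6], y2 = g[7];
    if (u <= t1) return y1;
    if (u <= t2) return Lmax * 1.3 * u / tau;
    if (u <= t3) return y2;
    if (u <= t4) return (y1 - y2) * (u - t3) / (t4 - t3) + y2;
    return y1;
}

/* core model equations; pp points at the 61 kinetic parameters, L1/L2 are the
 * (possibly gated) light inputs to the per1 / per2 transcript equations */
static void core_rhs(const double *pp, const double *y, double L1, double L2,
                     double *ydot)
{
    const double *vs = pp;        /* vs1..vs5   */
    const double *v  = pp + 5;    /* v1..v11    */
    const double *ke = pp + 16;   /* ke1..ke11  */
    const double *kd = pp + 27;   /* kd1..kd13  */
    const double *k  = pp + 40;   /* k1..k7     */
    const double *kp = pp + 47;   /* kp1..kp4   */
    const double *ka = pp + 51;   /* ka1..ka4   */
    double kI1 = pp[55], kx = pp[56], kk = pp[57];
    double m = pp[58], w = pp[59], s = pp[60];

    double Mp1 = y[0], Mp2 = y[1], P1c = y[2], P1n = y[3];
    double P2c = y[4], P2n = y[5], MB = y[6], Bc = y[7], BN = y[8];
    double MR = y[9], R = y[10], PB1 = y[11], PB2 = y[12];

    /* Mp1 */
    ydot[0] = vs[0] * hill_act(BN, ka[0], m)
            - v[0] * Mp1 / (ke[0] + Mp1) - kd[0] * Mp1 + L1;
    /* Mp2 */
    ydot[1] = vs[1] * hill_act(BN, ka[1], m)
            - v[3] * Mp2 / (ke[3] + Mp2) - kd[3] * Mp2 + L2;
    /* P1c */
    ydot[2] = k[0] * Mp1 - v[1] * P1c / (ke[1] + P1c) - kd[1] * P1c;
    /* P1n */
    ydot[3] = k[1] * P1c - v[2] * P1n / (ke[2] + P1n)
            + kp[0] * PB1 - kp[1] * P1n * BN - kd[2] * P1n;
    /* P2c */
    ydot[4] = k[2] * Mp2 - v[4] * P2c / (ke[4] + P2c) - kd[4] * P2c;
    /* P2n */
    ydot[5] = k[3] * P2c - v[5] * P2n / (ke[5] + P2n)
            + kp[2] * PB2 - kp[3] * P2n * BN - kk * P1n - kd[5] * P2n;
    /* MB: REV-ERBa repression (shared denominator reading) + PER2 activation */
    ydot[6] = vs[2] * kI1 * kI1 / (kI1 * kI1 + R * R + R * kx)
            + vs[3] * hill_act(P2n, ka[2], w)
            - v[6] * MB / (ke[6] + MB) - kd[6] * MB;
    /* Bc */
    ydot[7] = k[4] * MB - v[7] * Bc / (ke[7] + Bc) - kd[7] * Bc;
    /* BN */
    ydot[8] = k[5] * Bc - v[8] * BN / (ke[8] + BN)
            + kp[0] * PB1 - kp[1] * P1n * BN
            + kp[2] * PB2 - kp[3] * P2n * BN - kd[8] * BN;
    /* MR */
    ydot[9] = vs[4] * hill_act(BN, ka[3], s)
            - v[9] * MR / (ke[9] + MR) - kd[9] * MR;
    /* R */
    ydot[10] = k[6] * MR - v[10] * R / (ke[10] + R) - kd[10] * R;
    /* PB1 */
    ydot[11] = -kp[0] * PB1 + kp[1] * P1n * BN - kd[11] * PB1;
    /* PB2 */
    ydot[12] = -kp[2] * PB2 + kp[3] * P2n * BN - kd[12] * PB2;
}

void clock_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double Lseg = p[61];
    double L1 = Lseg, L2 = Lseg;
    if (p[62] > 0.5) {
        double tau = p[64];
        double u = fmod(*t - p[71], tau);
        if (u < 0) u += tau;
        L1 = 0.5 * p[63] * Lseg;      /* per1 gate: Lmax / 2 */
        L2 = gate2(u, p + 63) * Lseg; /* per2 gate: piecewise linear */
    }
    core_rhs(p, y, L1, L2, ydot);
}

/* Coupled two-cell model.
 * Parameters: 0..60 VL (morning) cell, 61..121 DM (evening) cell, then
 *   122 v_cm1 (AVP -> VL induction), 123 v_cm2 (VIP -> DM induction),
 *   124 k_vs1 (AVP production), 125 k_vs2 (VIP production),
 *   126 K_avp, 127 K_vip (saturation), 128 kd_avp, 129 kd_vip (clearance),
 *   130 beta (basal VIP production), 131 Lseg, 132..133 reserved.
 * State: 0..12 VL, 13..25 DM, 26 VIP, 27 AVP.
 */
void me_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double v_cm1 = cp[122], v_cm2 = cp[123];
    double k_vs1 = cp[124], k_vs2 = cp[125];
    double K_avp = cp[126], K_vip = cp[127];
    double kd_avp = cp[128], kd_vip = cp[129];
    double beta = cp[130], L = cp[131];
    double VIP = y[26], AVP = y[27];
    double ind_m, ind_e;

    /* AVP (from DM) induces per1/per2 in VL; light acts directly on VL */
    ind_m = v_cm1 * AVP / (K_avp + AVP);
    core_rhs(cp, y, L + ind_m, L + ind_m, ydot);
    /* VIP (from VL) induces per1/per2 in DM; no direct light */
    ind_e = v_cm2 * VIP / (K_vip + VIP);
    core_rhs(cp + 61, y + 13, ind_e, ind_e, ydot + 13);

    /* VIP produced in VL, driven by cytosolic PER1/2 and light */
    ydot[26] = beta + k_vs2 * (y[2] + y[4] + L) - kd_vip * VIP;
    /* AVP produced in DM, driven by cytosolic PER1/2 */
    ydot[27] = k_vs1 * (y[15] + y[17]) - kd_avp * AVP;
}
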