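# meclock

Simulation and analysis of a single-cell **dual morning/evening (ME)
oscillator** model of the mammalian circadian clock, for chronobiologists
and systems biologists who want a working, testable implementation of the
hypothesis that *per1* tracks dawn (morning oscillator) and *per2* tracks
dusk (evening oscillator) within one SCN cell.

## The model

The core is a 13-variable ODE system for the concentrations of *per1* and
*per2* mRNA (Mp1, Mp2), their proteins in cytosol and nucleus (P1c, P1n,
P2c, P2n), *Bmal1* mRNA and cytosolic/nuclear BMAL1 (MB, Bc, BN),
*Rev-erbα* mRNA and protein (MR, R), and the nuclear complexes PER1–BMAL1
and PER2–BMAL1 (PB1, PB2). Regulation follows the standard mammalian clock
architecture written with Hill activation, Michaelis–Menten degradation and
mass-action complexation, e.g. for *per1* mRNA

    dMp1/dt = vs1 BN^m/(ka1^m + BN^m) − v1 Mp1/(ke1 + Mp1) − kd1 Mp1 + L

with nuclear BMAL1 (BN) the activator of *per1*, *per2* and *Rev-erbα*,
REV-ERBα repressing *Bmal1* through vs3 kI1²/(kI1² + R² + R·kx), nuclear
PER2 coactivating *Bmal1* (the positive feedback vs4-term that makes the
evening limb special), and each nuclear PER sequestering BN into a complex.
Light L(t) is an *additive* production flux on the two per-mRNA equations
and can be gated per gene (constant Lmax/2 for *per1*; a piecewise-linear
circadian cycle peaking around CT 15–20 for *per2*).

On top of the single cell the package provides genotype presets (per1,
per2^ldc, per2^Brdm1, per1–per2, Bmal1, Rev-erbα knockouts), phase response
curves, entrainment analysis across photoperiods in the CT/ZT/InT/ExT
conventions, light and parameter bifurcation scans with Hopf bracketing,
period-sensitivity scans, a two-cell VL/DM model coupled by VIP and AVP
with molecular actograms and coupling-schedule (splitting-style)
protocols, and a seeded genetic algorithm for parameter estimation from
normalized time series.

The shipped parameter sets are calibrated by this package (see the methods
vignette, `vignettes/meclock-methods.Rmd`, for how and against which
hallmark quantities).

## Worked example

```r
library(meclock)

p  <- clock_params()                       # calibrated wild-type set
tr <- simulate_clock(p, light_dd(), t_end = 700, transient = 500)
glance(tr)
#> # A tibble: 1 × 7
#>   t_end transient genotype rhythm   period   period_sd n_peaks
#>   <dbl>     <dbl> <chr>    <chr>     <dbl>       <dbl>   <int>
#> 1   700       500 <NA>     rhythmic   23.7 0.000000213       8
```

`period = 23.67 h` is the free-running period in constant darkness
(calibrated toward the 23.75 h hallmark; see the vignette for the
residual); the
peak-phase table in circadian time (per1 mRNA peak ≡ CT 6) is obtained
with `detect_peaks()` + `to_circadian_time()`. A phase response curve and
a mutant comparison:

```r
prc <- compute_prc(p, "wild_type", amplitude = 0.35, ct_grid = 0:23)
glance(prc)        # maximal delay and advance with their circadian times
autoplot(prc)

p1 <- apply_mutant(p, "per1")              # per1 knockout (refit kinetics)
tr1 <- simulate_clock(p1, t_end = 700, transient = 500,
                      genotype = "per1")
estimate_period(detect_peaks(tr1, "Mp2"))  # shorter than wild type
```

The two-cell model and its molecular actogram:

```r
traj <- simulate_coupled(coupled_params(), protocol = light_dd(),
                         t_end_days = 40, transient_days = 25)
coupled_phase_difference(traj)   # common period ~23.6 h, M/E nearly in phase
act <- build_actogram(traj)
autoplot(act)                    # one fused daily bout
```

Coupling-parameter schedules (`coupling_schedule()`) express
splitting-style protocols; see the methods vignette for what the default
coupling forms do and do not reproduce.

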