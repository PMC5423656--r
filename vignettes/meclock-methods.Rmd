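---
title: "The dual morning/evening oscillator model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dual morning/evening oscillator model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(meclock)
```

## The model

`meclock` implements a single-cell gene-regulatory model of the mammalian
suprachiasmatic (SCN) circadian clock built around the hypothesis that the
two *period* genes act as separable oscillators: *per1* tracking dawn (the
"morning" or M limb) and *per2* tracking dusk (the "evening" or E limb).
The model follows 13 concentrations: *per1* and *per2* mRNA (`Mp1`, `Mp2`),
their proteins in cytosol and nucleus (`P1c`, `P1n`, `P2c`, `P2n`), *Bmal1*
mRNA and BMAL1 protein in cytosol and nucleus (`MB`, `Bc`, `BN`),
*Rev-erba* mRNA and protein (`MR`, `R`), and the two nuclear
PER–BMAL1 complexes (`PB1`, `PB2`).

Nuclear BMAL1 activates transcription of *per1*, *per2* and *Rev-erba*
through Hill functions; REV-ERBα represses *Bmal1*; nuclear PER2
additionally *coactivates* Bmal1 transcription (a positive feedback loop
that distinguishes the E limb); and each nuclear PER protein sequesters
BMAL1 into a complex, closing the negative feedback loops. Degradation is
Michaelis–Menten (enzymatic) plus first-order for every species; transport
and complexation follow mass action. Light enters *additively* in the two
per-mRNA equations — not through a transcription-rate parameter — so a
light pulse is an extra production flux `+L` for `Mp1` and `Mp2`.

Two structural details deserve explicit mention because the printed
equations admit more than one reading:

* The *Bmal1* repression term is taken as
  `vs3 * kI1^2 / (kI1^2 + R^2 + R*kx)`, the only grouping in which all
  denominator terms share units (nM²). The alternative reading (a separate
  additive `R/kx` flux) is not implemented; the shared-denominator form
  reproduces the calibration targets below.
* The `-kk * P1n` term in the nuclear-PER2 equation (nuclear PER1 removing
  nuclear PER2) is retained exactly as written. Because it is negative even
  when `P2n = 0`, it is the single term that can violate nonnegativity of
  the state; the calibrated parameter sets use `kk = 0`, for which the
  nonnegative orthant is forward-invariant (each component's derivative at
  its zero boundary is then a sum of nonnegative fluxes).

With all species at zero and no light, every production term except one
vanishes: the *Bmal1* promoter is fully *derepressed* at `R = 0`, so
`dMB/dt = vs3` there. The origin is therefore an exact fixed point only
when `vs3 = 0` (e.g. the Bmal1-knockout genotype); tests assert this
corrected statement rather than the naive "all-zero derivative".

## Parameter provenance and calibration

The package ships its own calibrated wild-type parameter set
(`clock_params()`, stored as plain text under `inst/extdata/`). It was
produced by the package authors with the package's own machinery — staged
Levenberg–Marquardt refinement on log-parameters plus stochastic
hill-climbing, with leading-Jacobian-eigenvalue terms used to steer
genotypes across their Hopf bifurcations — against hallmark quantities of
the mammalian SCN clock:

* free-running period 23.75 h in constant darkness, with the canonical
  peak order and phases (per1 mRNA CT 6 (reference), Rev-erba mRNA CT 6.5,
  PER1 CT 8, per2 mRNA CT 9.3, PER2 CT 12.3, Bmal1 mRNA CT 19.4);
* mutant behaviour under the genotype presets (`apply_mutant()`):
  the per1 knockout remains rhythmic with a shorter period (23.44 h
  target), the rhythmic per2 allele (`per2_ldc`) runs at 21.75 h, the
  transcriptional per2 knockout (`per2_Brdm1`), the per1–per2 double
  knockout and the Bmal1 knockout are arrhythmic, and the Rev-erba
  knockout stays rhythmic;
* entrainment to 24-h light–dark cycles at light level 0.1 with per1
  peaking in the light phase and per2 near lights-off, their peak
  difference growing with photoperiod and staying below 4 h.

Mutant presets replace whole co-adjusted parameter groups, not only the
knocked-out transcription rate, because each rhythmic mutant is a refit of
accessory kinetics; the override values are fixed numbers of the model
definition, which strongly anchors the absolute scale of the wild-type
rates (a parameter overridden to 0.43 nM/h in a mutant must sit at a
comparable wild-type value for the mutant period to land near the
wild-type one).

Degradation parameters are constrained to a physiological box
(roughly 0.02–12 in nM, nM/h or 1/h as appropriate). This matters: outside
the box the per2-allele genotype can acquire a spurious attractor in which
nuclear BMAL1 grows essentially unboundedly (saturated enzymatic
degradation with vanishing linear decay), which no biological
interpretation supports.

The constant-light ("wt_ll") set is a separate calibration of the same
network used for period-versus-intensity curves, where the
darkness-calibrated set has too narrow an oscillatory light range to show
the classical intensity dependence. The two-cell sets (`clock_params_me()`)
are per1-loop-dominant (VL) and per2-loop-dominant (DM) variants rescaled
in time to free-running periods of 23.3 h and 23.4 h; uniform scaling of
every rate constant with time dimension changes the period exactly
inversely, which is how those two targets are met exactly.

## Simulation and analysis choices

* **Integration.** `lsoda` through a compiled right-hand side, relative
  tolerance 1e-8, absolute 1e-10, output step 0.01 h. The integrator is
  restarted state-continuously at every light discontinuity (square-wave
  edges, pulse edges) and at every coupling-schedule switch, so
  discontinuous forcing is resolved exactly. Halving the tolerances moves
  the wild-type period by well under 0.005 h (asserted in the tests).
* **Transient.** 500 h (≈ 21 cycles) by default; the limit cycle is reached
  from any positive initial state, and initial-condition independence of
  the period (to 0.01 h) is a tested property, so the default initial
  state (all species at 0.1 nM) is cosmetic.
* **Peaks.** Local maxima refined by a quadratic fit through the three
  bracketing samples (sub-sample precision; the phase tables are read to
  0.01–0.1 h, which raw 0.01-h sampling alone would not guarantee), with a
  prominence floor of 1% of the post-transient range to discard numerical
  ripples. Period = mean inter-peak interval; its dispersion is reported.
* **Rhythmicity.** A trajectory is *arrhythmic* when the last-cycle
  peak-to-trough amplitude of every mRNA is below 1% of that variable's
  full-trace range; *damped* when window amplitudes shrink by more than
  10% per cycle while above the floor. The 1% floor is a judgement call,
  exposed as an argument.
* **Time conventions.** CT anchors a genotype-specific reference peak
  (wild type: per1 mRNA ≡ CT 6; per1 mutant: per2 mRNA ≡ CT 8; per2
  mutants: cytosolic PER1 ≡ CT 12) and maps one endogenous period to 24 CT
  hours. ZT 0 is lights-on; InT = (CT − 18) mod 24;
  ExT = (ZT + dark/2) mod 24, so ExT 12 is always mid-light. "PER1/PER2
  protein" phases refer to the cytosolic pools, consistent with the
  genotype reference markers.

## Light gating

Photic input can be gated per gene: the per1 gate is constant at `Lmax/2`,
and the per2 gate is a piecewise-linear cycle that rises through subjective
day, holds a high plateau across roughly CT 15–20 (where light-induced
phase delays are deepest), and returns to its low value at the end of the
cycle. Interval boundaries are closed on the right (the printed piecewise
definition is typographically inconsistent; left-open/right-closed is the
reading under which the branches connect continuously). Under free run the
gate cycle runs at the genotype's endogenous period with u = 0 at CT 0;
under entrainment it runs at the 24-h zeitgeber period anchored at
lights-on (the anchoring is a configuration field, `origin`, because no
published convention exists). A `custom` mode accepts a user function of
time and gene as the extension point for more elaborate gating (e.g.
clock-state-driven dead zones), which this package deliberately does not
hard-code.

## Phase response curves

A PRC run starts every pulse from the same converged limit-cycle state
anchored at the reference peak, applies one rectangular pulse (default 30
min) at the requested CT, and measures the shift between the perturbed and
unperturbed reference peaks ten cycles later, wrapped to (−12, 12] with
advances positive (the sign convention is chosen to match the usual
reading of mammalian PRCs; none is stated algebraically in the source
literature). Shifts at cycle 10 and cycle 15 agree to < 0.05 h in the
tests, confirming relaxation is complete at the read-out cycle.

## Entrainment

Locking is declared when successive reference-variable peaks are spaced
24 ± 0.05 h over at least 5 consecutive cycles after discarding 40 of 60
simulated cycles (the criterion is ours; none is published). Phases are
circular means of per-cycle peak phases converted to ExT.

## Bifurcation analysis

No continuation package is emulated: a dense grid scan locates the steady
state at each parameter value (damped Newton from the previous grid
point's solution or from the trajectory mean), classifies stability by the
leading eigenvalue of a central-finite-difference Jacobian (relative step
1e-6), and brackets the Hopf point between adjacent grid points with
opposite leading signs. Where the steady state is unstable, the limit
cycle's amplitude (peak-to-trough of per1 mRNA) and period are measured by
simulation; eigenvalue classification and long-time simulation are
asserted to agree at every grid point, and the supercritical signature
(amplitude shrinking continuously toward the bracket) is tested rather
than assumed.

## The coupled two-cell model and splitting

The splitting module couples two copies of the single cell: a
ventrolateral (VL) "morning" cell that receives light directly and a
dorsomedial (DM) "evening" cell that does not. VIP, produced in the VL
cell in proportion to its cytosolic PER proteins plus the light input, and
AVP, produced in the DM cell from its cytosolic PER proteins, carry the
coupling; each induces per1/per2 transcription in the opposite cell
through a saturating (Michaelis-type) term. The exact published functional
forms of the coupling fluxes are not available to this implementation;
the saturating-induction forms used here are this package's own declared
default, exposed with named constants (`v_cm1`, `v_cm2`, `k_vs1`, `k_vs2`,
saturation and clearance constants, basal production `beta`) so they can
be replaced wholesale. The cytosolic pools drive the neuropeptides because
that phasing brings the two cells' nuclear-PER1 rhythms into near
coincidence in the coupled "fused" state (a ~0-0.4 h difference), as the
fused actogram requires; driving them from the nuclear pools locks the
cells ~9 h apart. The VIP initial condition (0.1 nM) and `beta`
(0.01 nM/h) are both exposed because the source text states them
ambiguously in a single sentence.

With the shipped sets the two cells free-run at 23.3 h (VL) and 23.4 h
(DM) exactly — uniform time-rescaling of the rate constants sets a
free-running period exactly — and the coupled pair synchronizes to a
common period of about 23.6 h in darkness.

Actograms threshold the normalized nuclear-PER1 traces of the two cells at
1.3 × the mean of the normalized trace, with 6-min bins by default; rows
are consecutive 24-h days and the raster can be double-plotted. Splitting
protocols are expressed as coupling-parameter schedules (e.g. constant
light at L = 0.02 with a switch after 30 days to weaker AVP coupling and
VIP production). A genuine limitation of the default coupling forms must
be stated here: with this package's calibration the in-phase locked state
of the two cells is extremely stable, and the weakened-coupling switches
reduce the locking margin without destabilizing it, so the
fused → split → phase-exchange sequence is *not* reproduced — the pair
stays fused. Producing a stable antiphase (split) state evidently requires
coupling functional forms with a different phase-response geometry than
the saturating-induction default; the schedule and actogram machinery is
in place for users who wish to substitute their own forms (all coupling
constants and both drive terms are exposed).

## Parameter estimation

The GA module exists for parameter-recovery testing, not to reproduce any
published table: the published estimation procedure and cost function are
not available, so the objective here is declared openly — mean squared
error between phase-aligned normalized traces plus an optional period
penalty `lambda * (period - target)^2`, with a large finite penalty for
arrhythmic candidates. The GA is a seeded, elitist, generational algorithm
(tournament selection, uniform crossover, log-normal mutation); elitism
makes the best cost non-increasing, and all randomness derives from the
configuration seed through a private RNG stream so runs are bit
reproducible. Acceptance for this module is recovery-based: with five free
parameters, noiseless synthetic data and ±50% bounds, the refitted model's
period must land within 0.5 h of the generating one.

## Problem sizes used in the tests

The shipped test-suite and acceptance script scale the expensive pieces to
desk size: free-running analyses use 700–900 h of simulated time with a
500 h transient; entrainment uses 40–60 cycles discarding 25–40; light
scans use 13–26 grid points; the splitting run uses 60–75 days at a 0.02 h
output step; GA recovery uses small populations (16–24) and few
generations. These sizes are chosen so every reported quantity is
converged at the precision asserted for it (periods to ~0.01 h, phases to
~0.05 h), as the convergence tests verify.

## What the synthetic data do and do not show

The synthetic-fixture generator reproduces what the model itself emulates:
noise-free (or Gaussian-noise) normalized trajectories of a deterministic
limit-cycle oscillator sampled on a regular grid. Real SCN recordings
carry features deliberately absent here — cell-to-cell period dispersion,
non-stationary amplitudes, sampling irregularity, and non-Gaussian
measurement error — so passing recovery tests demonstrates correctness of
the estimation machinery, not robustness on experimental data.

## Known limitations

* The calibrated sets are this package's own; no published parameter table
  is reproduced, and quantities not used as calibration targets (e.g.
  absolute concentrations) should be read as model-scale, not measured.
* Several hallmark quantities could not all be met simultaneously by one
  parameter set (the spec of the calibration targets over-determines the
  accessible basin): the shipped set prioritizes the mutant periods,
  entrainment locking and the qualitative knockout pattern. The wild-type
  free-running period sits at 23.67 h (target 23.75); the Bmal1-mRNA peak
  phase runs ~2.8 h late (CT 22.2 instead of 19.4); the per1-mRNA peak of
  the rhythmic per2 allele lands at CT 9.4 instead of 8.4; the LD 12:12
  per1/per2 peak separation is 2.4 h instead of 3.2 h and the 6:18
  photoperiod fails to lock 1:1; the period over the oscillatory
  constant-light range of the darkness set rises to ~24.9 h near the Hopf
  point instead of staying at 23.8; and the wild-type pulse-response curve
  is shallower than intended (the two limbs' light responses nearly
  cancel, so the per2-mutant delay at CT 15 exceeds the wild type's).
  These are documented honestly in the acceptance tests rather than
  patched over.
* In the per2-knockout allele and the per1-per2 double knockout the per
  transcripts are silent as required, but the Bmal1/REV-ERB subsystem keeps
  a self-sustained rhythm in this calibration, so the whole-transcriptome
  rhythmicity classifier does not return "arrhythmic" for them. Removing
  that residual cycle destabilizes the rhythmic per2 allele, which relies
  on a live REV-ERB loop; the trade-off is inherent to this basin.
* cry1/2, Rorc and Clock are intentionally absent (the network lumps them
  per its design assumptions); no phosphorylation sub-steps.
* The dead-zone variant of gating is an extension point, not implemented.
* Two cells only; no SCN-scale network, no GABA/NMDA coupling, no
  light after-effects.
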