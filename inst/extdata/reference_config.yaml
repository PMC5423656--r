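# Reference run configuration for meclock with all defaults spelled out.
# Every pipeline reads the same top-level fields; the per-command blocks
# below list the options each command understands.

command: simulate        # simulate | prc | entrain | llscan | bifurcate |
                         # sensitivity | split | actogram | fit | synth
genotype: wild_type      # wild_type | per1 | per2_ldc | per2_Brdm1 |
                         # per1_per2 | bmal1 | rev_erba
params_file: null        # key-value file (symbol = value); null = shipped
                         # calibrated set
params_set: wt_dd        # wt_dd | wt_ll (ignored when params_file given)
protocol:
  kind: dd               # dd | ll | ld | pulse
  L: 0.02                # ll: constant intensity
  light_h: 12            # ld: light phase duration (24 h cycle)
  L_on: 0.1              # ld: light-phase intensity
  start: 14.0            # pulse: onset (h)
  duration: 0.5          # pulse: duration (h)
  amplitude: 0.2         # pulse: amplitude
gating: none             # none | per_gene
gating_tau: 24           # reference period of the gating cycle
t_end: 700               # simulate: end time (h)
transient: 500           # simulate: transient discard (h)
seed: 1                  # all randomness (fit/synth) derives from this
outdir: results

# prc:        amplitude (0.35), duration (0.5), ct_grid (0..23)
# entrain:    light_h (12), L_on (0.1)
# llscan:     L_values (list of intensities)
# bifurcate:  parameter ("L" or a symbol), grid (list of values)
# sensitivity: delta (0.05), subset (list of symbols; null = all)
# split/actogram: t_end_days (60), transient_days (10), threshold (1.3),
#             bin_h (0.1), schedule (list of {day, v_cm1, v_cm2, k_vs1,
#             k_vs2} blocks)
# fit:        free (symbols), noise_sd (0)
# synth:      noise_sd (0)
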