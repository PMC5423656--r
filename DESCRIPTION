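Package: meclock
Title: Single-Cell Dual Morning/Evening Oscillator Model of the Mammalian
    Circadian Clock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a 13-variable gene-regulatory ODE
    model of the mammalian suprachiasmatic clock in which per1 and per2 act
    as morning and evening oscillators. Provides light protocols and
    per-gene gating of photic input, mutant genotypes, peak/period/phase
    analysis in the CT/ZT/InT/ExT conventions, phase response curves,
    entrainment across photoperiods, constant-light period curves, Hopf
    bifurcation scans and period sensitivity, a two-cell VIP/AVP-coupled
    model with splitting simulations and molecular actograms, and
    genetic-algorithm parameter estimation from normalized time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
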