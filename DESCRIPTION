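Package: entrainlock
Title: Phase Entrainment Analysis for Rhythmic TMS-EEG Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse phase entrainment of cortical
    oscillations by rhythmic transcranial magnetic stimulation (rTMS)
    recorded with EEG. Provides a seeded generator of multi-trial TMS-EEG
    epochs with pulsed phase-oscillator dynamics (phase reset, progressive
    entrainment, sham), a TMS artifact preprocessing pipeline (pulse-window
    interpolation, ICA decay suppression, amplitude-based trial rejection,
    spherical-spline current source density, downsampling), Morlet wavelet
    time-frequency decomposition, inter-trial phase-locking statistics
    (PLF, the Rayleigh-Z bias-corrected ZPLF and its normalizations), and a
    nonparametric statistical battery: cluster-based permutation tests over
    electrode-frequency-time maps, significant-electrode counting with
    binomial tests, one-way ANOVA with Dunnett many-to-one comparisons, and
    Pearson trend tests over stimulation pulses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    signal,
    mvtnorm,
    igraph
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
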