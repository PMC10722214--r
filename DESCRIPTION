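Package: fibronet
Title: Network-Coupled Atrial Tissue Simulation with Stochastic Calcium
    Release and Patchy Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-dimensional atrial tissue simulator for studying how patchy
    fibrosis promotes both the triggers and the substrate of atrial
    fibrillation.  Couples a minimal atrial action-potential model (with an
    externally imposed ryanodine-receptor open-fraction drive, plus atrial
    fibrillation remodelling, sympathetic stimulation, and myocyte-fibroblast
    coupling modifiers) to an orientation-weighted network model of
    inter-cellular coupling on a structured grid.  Spontaneous calcium release
    events are represented by a reduced stochastic model: analytic spike and
    plateau waveforms of the whole-cell ryanodine-receptor open fraction whose
    timing and duration are sampled through skewed two-branch sigmoidal
    inverse cumulative distributions.  Fibrotic substrates are generated from
    thresholded Gaussian random fields, with preferential random removal of
    transverse inter-nodal connections inside patches.  Protocol drivers
    quantify focal-excitation probability, re-entry induction under rapid
    pacing, sinus-rhythm interruption, conduction velocity and activation
    maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
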