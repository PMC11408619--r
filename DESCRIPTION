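Package: smfs
Title: Single-Molecule Magnetic Force Spectroscopy Analysis of Riboswitch Folding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-molecule magnetic force spectroscopy (MFS)
    experiments on ligand-responsive RNA structures such as riboswitch
    aptamers. Provides force-ramp pipelines (quality control, ramp-cycle
    segmentation, rupture-event detection by density clustering with a
    changepoint oracle, structure selection, per-bead force normalization and
    high-force-fraction statistics), constant-force pipelines (two-state
    hidden-Markov state assignment, dwell-time extraction,
    exponential-mixture maximum likelihood with BIC model selection, and
    rate aggregation across molecules), dose-response fitting (EC50, KD and
    T50 saturation models), and a mechanistic trace simulator with Bell-Evans
    force-dependent kinetics covering both thermodynamic (stable-fold
    induction) and kinetic (unfolding-rate reduction) modes of ligand action.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
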