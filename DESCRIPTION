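Package: trailscreen
Title: Arrayed RNAi Screen Analysis for Regulators of TRAIL-Induced Apoptosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for arrayed siRNA screens of death-receptor
    (TRAIL) signaling read out by caspase-8 activity, caspase-3/7 activity and
    cell viability on 384-well plates. Implements per-plate fold-change
    normalization against non-targeting control wells, control-derived
    standard-deviation thresholds with an m-of-n siRNA redundancy rule and two
    stringency tiers, direction-specific gene calls with multi-assay
    corroboration, cross-assay correlation and Z-factor quality control,
    secondary-screen summary matrices, and degree-based hub extraction from a
    user-supplied interaction network. A synthetic screen generator with
    planted regulators and per-reagent efficacy heterogeneity supports
    end-to-end testing and recovery benchmarking without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
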