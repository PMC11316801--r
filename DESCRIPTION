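Package: codedrift
Title: Longitudinal Stability of Task-Variable Coding in Cortical Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying representational drift in
    chronic two-photon calcium imaging of behaving mice. Converts raw soma
    and neuropil fluorescence into neuropil-corrected dF/F traces, applies
    behavioral, reliability and ROI-morphology inclusion gates, decodes
    binary task variables (context, motor choice, post-decision and
    post-trial outcome) per time bin with linear support-vector classifiers
    trained on a reference day, and quantifies cross-day coding stability by
    fitting exponential decay time constants to window-integrated,
    day-1-normalized decoding performance. Includes a synthetic multi-day
    experiment generator (virtual T-maze trial schedules, drifting tuning,
    calcium-like transients, neuropil contamination, ROI image patches) with
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
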