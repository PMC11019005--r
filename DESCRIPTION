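Package: sstdbm
Title: Dynamic Belief Modeling of Proactive Inhibitory Control in the
    Stop-Signal Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for model-based analysis of the motivated stop-signal
    task with concurrent EEG. Implements a Dynamic Belief Model (DBM) that
    infers a trial-wise stop-signal expectation P(stop) from the trial-type
    history via a leaky beta-Bernoulli filter, and fits its parameters per
    subject and condition block by exhaustive grid search maximizing the
    robust linear-regression fit of Go reaction times on P(stop). Includes
    a synthetic-data generator for the task (adaptive stop-signal-delay
    staircase, race-model agent with expectation-driven slowing, single-
    trial P1/N1 waveform rendering), single-trial ERP feature extraction
    (baseline correction, artifact screening, windowed peak detection,
    two-channel combination), race-model SSRT estimation by the integration
    method, and trial-level mixed-effects models linking motivation
    condition and P(stop) to attention ERPs and stop performance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
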