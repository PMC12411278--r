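Package: voltfield
Title: Analysis of Trial-Structured Voltage-Imaging and Extracellular Recordings
Version: 0.9.0
Authors@R:
    person("Volt", "Field", email = "maintainer@voltfield.org", role = c("aut", "cre"))
Description: Tools for analysing trial-structured recordings of hippocampal
    neurons during an odor-cued delayed non-match-to-sample (DNMS) task:
    detection of odor-onset hyperpolarization events in voltage-imaging
    (dF/F) traces, temporal firing-field detection with a circular-shift
    permutation null, odor selectivity indices, Bayesian decoding of
    odor-specific time with a Poisson emission model and continuity prior,
    multiday field-turnover statistics, fine-timescale onset/rebound
    spiking metrics, and companion extracellular procedures (LFP
    conditioning, sharp-wave-ripple detection, waveform-based unit
    classification, odor responses).  A synthetic-data generator with full
    ground truth stands in for raw recordings and drives calibration and
    power tests of every detector.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
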