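Package: fibercouple
Title: Dual-Color Fiber Photometry Analysis and Neuron-Astrocyte Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for dual-color fiber photometry recordings
    of two genetically encoded calcium indicators with isosbestic control
    channels. Provides polynomial baseline detrending, isosbestic motion
    correction, zero-phase low-pass filtering and z-scoring; event-aligned
    trial extraction with bout-length, event-count, baseline-irregularity and
    trial-cap quality control; per-trial peak, time-of-peak, area-under-curve
    and epoch-mean metrics; trial-wise neuron-astrocyte coupling regression;
    behavioral classification of looming-shadow responses and social sniff
    summaries; and the accompanying statistical battery (exact nonparametric
    tests, repeated-measures and two-way ANOVA, two-stage linear step-up
    false-discovery-rate control, robust outlier removal). A fully
    parameterized synthetic dual-sensor session generator makes every stage
    verifiable by ground-truth parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    pracma,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
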