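Package: cardiobcg
Title: Closed-Loop Cardiovascular Modelling and Ballistocardiogram Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lumped-parameter (0D) closed-loop model of the human
    cardiovascular system with two time-varying-elastance ventricles, a
    segmented systemic arterial tree, microcirculation, venous return and a
    pulmonary loop. The package is built as a virtual laboratory for
    sex-difference experiments: it ships idealized male and female
    parameterizations plus six single-parameter intermediates, computes
    ventricular volumetric outputs and ventricular-arterial coupling
    indexes, synthesizes the ballistocardiogram (BCG) force waveform from
    the simulated redistribution of blood volume, and provides a
    Butterworth-filter / R-peak segmentation / ensemble-averaging pipeline
    for processing paired ECG+BCG recordings, testable end-to-end on
    synthetic recordings with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
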