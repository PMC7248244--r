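Package: neuroloop
Title: Critic-Actor Adaptive Deep Brain Stimulation Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for closed-loop (adaptive) deep brain
    stimulation driven by parkinsonian state estimates. Provides a
    semi-synthetic local field potential (LFP) generator built on ARMA
    models with controllable PD/non-PD band-power separation, a black-box
    stimulation-frequency-driven modulating network, overlapping band-power
    feature extraction with maximum-ratio band selection, linear-kernel SVM
    and two-Gaussian generative state estimators emitting PD-severity
    probabilities, Mamdani fuzzy controllers (min inference,
    center-of-gravity defuzzification) that adjust stimulation frequency,
    a closed-loop orchestrator, and evaluation metrics (Matthews
    correlation coefficient, weighted classification error, settling time,
    bit-level operation counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
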