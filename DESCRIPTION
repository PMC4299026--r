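Package: ecgtriage
Title: Early Triage of Pathological Heartbeats for Embedded ECG Monitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time-oriented classification of single-lead ECG heartbeats
    into normal and pathological (premature ventricular contraction, left
    bundle branch block) classes, as deployed on wireless body sensor nodes.
    Provides a synthetic labeled-beat generator, morphological baseline
    filtering and wavelet R-peak detection, dimensionality reduction by
    sparse ternary (Achlioptas) random projection, principal component
    analysis or wavelet fiducial-point delineation, a trainable gaussian
    neuro-fuzzy classifier with an alpha-thresholded defuzzification rule,
    a genetic algorithm that optimizes the projection matrix jointly with
    the classifier, an integer-only quantized inference path mirroring
    microcontroller constraints (piecewise-linear membership functions,
    shift-truncate fuzzification, division-free defuzzification), and
    evaluation by Normal Discard Rate and Abnormal Recognition Rate with
    cross-validation, Pareto sweeps and baseline comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
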