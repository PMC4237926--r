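Package: facescore
Title: Psychometric Scoring of Automated Facial Emotion Expression Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning frame-level automated facial-expression codes
    (simplex-constrained emotion proportions plus action-unit intensities, as
    produced by coders in the CERT/FACET family) into psychometric ability
    scores. Implements trial-level missing-data filtering, iterative
    Mahalanobis outlier replacement, loess smoothing with AIC/AICc/GCV
    bandwidth selection, four competing trial scores (arithmetic mean,
    geometric mean, average area under the curve, maximum), baseline-emotion
    and facial-plasticity residualization, split-half reliability reporting,
    and a synthetic session generator with known ground truth for method
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
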