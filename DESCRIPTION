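Package: sddsgd
Title: Step-Wise Dual Dynamic Differentially Private SGD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements step-wise dual dynamic differentially private
    stochastic gradient descent (SDD-DPSGD), in which training is divided
    into geometrically growing stages while the noise multiplier grows and
    the per-sample clipping threshold decays geometrically. Provides the
    schedule constructor with its protection-horizon stage-count rule, a
    Renyi differential privacy accountant with composition, conversion to
    (epsilon, delta)-DP and budget calibration, reference trainers (softmax
    regression and a one-hidden-layer perceptron) with exact per-sample
    gradients, a synthetic class-imbalanced Gaussian-mixture data generator,
    and imbalance-aware evaluation (Matthews correlation coefficient, macro
    F1, few-shot versus large-shot group accuracy) with a seed-replicated
    comparison runner against a static DPSGD baseline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
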