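Package: elmqsar
Title: Efficient Linear Method for Binary QSAR Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the efficient linear method (ELM) for binary
    quantitative structure-activity relationship (QSAR) classification of
    aromatase inhibitors and similar descriptor-based activity data. A
    binary-chromosome genetic algorithm with a Welch t-test prefilter and an
    AIC fitness selects informative molecular descriptors and ranks them by
    usage frequency in the final population; a no-intercept weighted-sum
    score is initialized by closed-form univariate least squares and refined
    by a real-coded genetic algorithm maximizing a robust Andrews' sine
    fitness; classes are assigned by comparing the score to a class-mean
    threshold. Includes confusion-matrix metrics (accuracy, sensitivity,
    specificity, Matthews correlation coefficient), stratified k-fold
    cross-validation, a repeated-experiment protocol with mean and standard
    deviation reporting, a synthetic descriptor-table generator with planted
    informative descriptors, and a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
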