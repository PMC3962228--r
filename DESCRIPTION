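Package: adaptsel
Title: Adaptive and Static Compound Selection for QSAR Experimental Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Training-set selection for quantitative structure-activity
    relationship (QSAR) modelling. Implements the stepwise adaptive DescRep
    strategy (endpoint-correlated descriptor selection alternating with
    representativeness-based batch compound selection), PLS-Optimal, and the
    classic static designs (Kennard-Stone, D-Optimal with Fedorov exchange,
    space-filling, most-descriptive-compound, random), together with a
    robustness-evaluation harness: repeated design/validation splits, partial
    least squares models with cross-validated component choice, dispersion and
    selection-variability statistics, structural-outlier injection and the
    paired sign (binomial) test. A synthetic descriptor-table generator with
    sparse group-count descriptors makes the whole pipeline testable without
    external descriptor software.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
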