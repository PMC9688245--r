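Package: fallfs
Title: Filter-Ensemble Feature Selection for Fall-Risk Detection in Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting fall risk in people with Multiple Sclerosis
    from mixed metric/ordinal gait and questionnaire data. Implements a
    filter-based feature-selection ensemble (chi-square, information gain,
    minimum-redundancy maximum-relevance and ReliefF rankings combined by
    rank thresholds and set-combination rules), type-aware preprocessing
    (median/mode imputation, knowledge-based EDSS handling, standardization),
    four reference classifiers evaluated under repeated stratified
    cross-validation with permutation-test significance, and a synthetic
    multi-block cohort generator that emulates the statistical structure of
    a multidimensional clinical gait assessment so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
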