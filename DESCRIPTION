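Package: handtwin
Title: Handedness Laterality Scoring and Twin-Based Heritability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hand-preference and hand-performance data in
    classical twin designs. Scores a 10-item Edinburgh-style handedness
    inventory into laterality quotients (EHI) and binary direction measures,
    computes pegboard laterality indices (PegQ) from timed trials, runs the
    prevalence contingency analyses (Pearson chi-square tests with Bonferroni
    correction, reliability and cross-measure correlations), and estimates
    additive-genetic (A), shared-environmental (C) and non-shared (E) variance
    components by full-information maximum likelihood: univariate ACE/AE/CE/E
    comparison for continuous and binary (liability-threshold) traits, and the
    bivariate Cholesky ladder with correlated-factors conversion. A seeded
    synthetic twin/singleton cohort generator makes the whole pipeline
    testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mvtnorm,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
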