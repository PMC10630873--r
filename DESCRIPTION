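Package: qdscore
Title: Quantitative Difference Scoring of Paired Clinical Laboratory Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the quantitative difference (QD) algorithm for
    evaluating therapeutic efficacy from paired pre- and post-treatment
    clinical laboratory panels, as proposed for acute-on-chronic liver
    failure. Per-indicator change is scored by direction, by a
    golden-section ("golden logarithm") magnitude bucketing of the max/min
    ratio, and by a reference-interval correction; a gated modification of
    the four liver-function indicators yields a composite per-patient
    score. The Model for End-Stage Liver Disease (MELD) score is provided
    as the comparator. A seeded synthetic-cohort generator with
    log-normal laboratory marginals, cohort input/output in a delimited
    long format, and cohort-level comparison statistics (paired tests,
    group summaries, score correlation) make every pipeline stage testable
    without patient data. Cohorts are represented as a
    SummarizedExperiment-derived container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
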