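Package: SalivaClock
Title: Circadian Profiling of Core-Clock Gene Expression in Saliva Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying circadian rhythms from sparse human saliva
    time courses. Converts qPCR cycle-threshold tables for core-clock genes
    (ARNTL1, PER2, NR1D1) into relative expression via the Livak delta-delta-CT
    scheme, fits fixed-period (24 h) harmonic regressions with likelihood-ratio
    and exact F rhythmicity tests, fits salivary cortisol profiles by robust
    soft-L1 harmonic regression, computes day-to-day reproducibility metrics
    (MAE, MSE, RMSE, MBE, paired Wilcoxon with Bonferroni correction),
    cross-layer association statistics (Spearman matrices, mutual information,
    maximal information coefficient, cell-composition ratios, chronotype
    classification), and evaluates reduced sampling designs by Monte-Carlo
    subsampling of dense circadian series. A synthetic-cohort generator with a
    known truth table makes every stage testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
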