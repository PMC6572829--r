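Package: combobench
Title: Loewe Synergy Scoring and Benchmarking for Drug Combination Screens
Version: 0.1.0
Authors@R: person("Combobench", "Developers", role = c("aut", "cre"),
    email = "maintainer@combobench.dev")
Description: Tools for analysing dose-matrix drug combination screens in
    cancer cell line panels. Fits Hill monotherapy curves, builds
    Loewe-additive reference surfaces, and integrates the synergy
    distribution in log-concentration space to a single capped score.
    Implements community-benchmark scoring of synergy predictions
    (weighted Pearson correlation, sequential three-way ANOVA, balanced
    accuracy, paired-bootstrap Bayes factors, permutation null models and
    replicate upper bounds), label-free ensembling of binary predictors
    via the spectral meta-learner, pharmacogenomic biomarker association
    analyses against binary event matrices, and in-vivo/in-vitro
    combination benefit class mapping. A fully seeded synthetic screen
    generator produces every input the pipeline consumes, with known
    ground-truth synergy, so the whole stack is testable without any
    data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
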