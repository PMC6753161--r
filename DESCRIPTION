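Package: grsreward
Title: Genetic Risk Scores and Stress-Induced Reward-Learning Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links a weighted depression genetic risk score (GRS) built from
    GWAS summary statistics to anhedonia-related phenotypes across units of
    analysis: self-report, probabilistic-reward-task (PRT) signal-detection
    behavior, Q-learning reward-prediction-error signals, and striatal
    volumetry.  Provides genotype quality control, effect-allele
    harmonization, weighted allele-dosage scoring, genotype principal
    components for ancestry adjustment, signal-detection response bias and
    its stress-induced change score, Q-learning/softmax simulation, RPE
    regressor generation and maximum-likelihood parameter estimation, and
    hierarchical regression with incremental-variance (change-in-R-squared /
    F-change) tests.  A calibrated synthetic-cohort generator reproduces the
    statistical structure the analysis assumes, so every stage can be
    exercised and validated end to end without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
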