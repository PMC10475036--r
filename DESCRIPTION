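Package: sociallearn
Title: Valence-Asymmetric Social Learning of Self-Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of social-feedback learning of
    self-evaluation and state self-esteem. Implements a valence-split
    feedback-learning model of self-evaluation change, an asymmetric
    Rescorla-Wagner model of trial-wise state self-esteem fitted by
    bound-constrained least squares with BIC model comparison, group-level
    inference (paired and Welch t-tests with effect-size conventions,
    Pearson, Spearman and partial correlations, Fisher-z, robust Huber
    regression), trial-level multilevel mediation with bootstrap inference,
    and similarity scoring of contrast vectors against binary network
    masks. Ships a seeded synthetic-cohort generator that emulates a
    two-group (social anxiety vs. control) speech-feedback task with known
    ground-truth parameters for recovery and calibration testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
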