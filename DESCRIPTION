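Package: coinlab
Title: Simulation and Ideal-Observer Analysis of a Bayesian Coin-Catching Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the "coin task", a visuomotor decision paradigm in which
    observers locate a hidden target by combining noisy sensory evidence (five
    splash positions) with a blockwise prior over target location. Provides the
    task-design generator (2x2 prior-by-likelihood Gaussian structure and a
    likelihood-only calibration task), a synthetic cohort simulator of noisy
    Bayesian observers whose subjective variances covary with a psychotic-like
    experience trait, closed-form per-participant estimators (sensory-weight
    regression, sensitivity to prior change, trial-wise weights, subjective
    likelihood and prior variances, Bayesian-optimal benchmarks, outlier
    exclusion), and a group-level inference layer (bootstrap correlations,
    Bonferroni adjustment, Wilcoxon tests against optimality, paired t tests,
    two-way ANOVA, and correlation power analysis) with a reproducible
    end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
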