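Package: affectlba
Title: Hierarchical Bayesian Linear Ballistic Accumulator Modelling of
    Affective Reports Under Anticipated Effort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for treating anticipated task effort as emotional
    evidence in two-choice pleasant/unpleasant feeling reports. Implements
    the closed-form linear ballistic accumulator (LBA) race likelihood with
    a normative and an aberrant accumulator, a four-step reaction-time
    preprocessing pipeline with audit reports, hierarchical Bayesian
    estimation of subject- and population-level LBA parameters by
    differential-evolution MCMC, Gelman-Rubin convergence checks and
    participant-summed DIC model comparison, default-prior Bayes-factor
    inference (JZS paired t-tests and 2x2 repeated-measures Bayesian ANOVA)
    on the fitted drift rates, and a synthetic-experiment generator
    emulating a 2x2 picture-pleasantness by search-difficulty design for
    end-to-end parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
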