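Package: rpcohort
Title: Risk-Period-Cohort Models for Age-Period-Cohort Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@rpcohort.org",
           role = c("aut", "cre"))
Description: Fits risk-period-cohort (RPC) regression models, an
    alternative to classical age-period-cohort (APC) analysis that
    replaces chronological age with a model-derived age-related risk
    index, thereby breaking the exact linear dependency age = period -
    cohort that makes APC effects jointly inestimable.  Provides the
    internal risk model and its admissibility diagnostics (age-risk
    correlation against a multicollinearity threshold, proportionate
    chronological age effect), fixed-effects RPC and traditional APC
    regressions with reference-level handling and a minimum-norm solver
    for near-singular designs, a hierarchical variant with crossed
    random intercepts for period and cohort estimated by REML, fast
    Monte Carlo drivers that evaluate correlation behaviour and
    cohort/period-effect recovery over full slope-parameter grids, and
    generators for the simulation designs including a synthetic
    survey-like panel with a skewed bounded questionnaire score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    lme4,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
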