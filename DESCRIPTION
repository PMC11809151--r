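Package: cohortsynth
Title: Sequential Synthesis, Disclosure Control and Release Auditing for
    Cohort Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for releasing synthetic versions of restricted cohort
    datasets. Implements sequential conditional synthesis (marginal
    resampling for the first variable, CART donor sampling or parametric
    draws for the rest, with deterministic rules and kernel smoothing),
    statistical disclosure control (replicated-unique detection and
    removal, top/bottom coding, manual spot checks), utility validation
    (marginal comparisons and refitted-model coefficient comparisons on a
    common z-value scale), multilevel quadratic growth-curve validation of
    repeated-measures panels, a ground-truth fixture generator emulating
    birth-cohort analysis datasets, and release packaging with a FALSE_DATA
    marker column, disclaimer and provenance, plus a guideline audit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rpart,
    nnet,
    lme4,
    haven,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
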