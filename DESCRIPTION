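Package: leanmass
Title: Multifrequency Bioimpedance Prediction of Appendicular Lean Mass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating bioelectrical-impedance
    prediction equations for appendicular lean mass (ALM) against a DXA
    reference. Computes multifrequency impedance and resistance indices
    (height squared over Z or R), evaluates published and user-supplied
    prediction equations, runs per-frequency bivariate regression scans and
    p-value based stepwise multiple linear regression with variance-inflation
    screening, and reports the standard method-comparison battery: standard
    error of estimate, total error, coefficient of variation, percentage of
    individual agreement, subjective rating bands, paired t-tests,
    line-of-best-fit analysis and Bland-Altman limits of agreement. Includes
    AWGS-cutoff sarcopenia classification with Cohen's kappa agreement
    statistics, and a seedable synthetic cohort generator calibrated to
    published sex-stratified moments so the whole pipeline is testable
    without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
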