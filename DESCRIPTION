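Package: ipssirt
Title: Item Response Theory and Longitudinal Modelling of the International
    Prostate Symptom Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pharmacometric item-response-theory analysis of the seven-item
    International Prostate Symptom Score (IPSS) in benign prostatic
    hyperplasia trials. Implements Samejima graded-response item
    characteristic curve estimation by marginal maximum likelihood under an
    independent-visit (IDVIS) scheme with post-baseline latent shift
    parameters, in one or two latent dimensions; Fisher-information item
    ranking; empirical Bayes disability estimation with standard errors;
    nonlinear mixed-effects models for total IPSS and latent disability
    (placebo time-course with optional Weibull shape and drift, offset drug
    effect, stepwise covariate search, the sequential PSI-IPPSE stage and the
    joint item-level model); eta-sampling GAM item-characteristic-curve
    diagnostics, visual predictive checks and residual item correlations; and
    a type-I-error-calibrated stochastic-simulation-and-estimation power
    engine benchmarked against cross-sectional and while-on-treatment ANCOVA.
    A trial simulator generates synthetic item-level datasets with the design
    of a four-arm, 403-patient dose-finding study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
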