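Package: svypate
Title: Survey-Weighted Estimation of the Population Average Treatment Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of the population average treatment effect (PATE) from
    complex-survey data: inverse probability of treatment weighting (IPTW) with
    survey-by-treatment weight combination, G-computation (standardisation) with
    survey-weighted outcome models and Monte Carlo counterfactual prediction, and
    targeted maximum likelihood estimation (TMLE) with a clever-covariate
    targeting step. Includes design-aware weighted regression with linearization
    (sandwich) variance, percentile and Rao-Wu-Yue bootstrap confidence
    intervals, covariate balance and positivity diagnostics, four reference
    regression baselines, a synthetic survey-data generator with known causal
    truth for validation, and an adapter that assembles NHANES-style
    public-release files into an analysis dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    foreign
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
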