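---
title: "Estimating the population average treatment effect from complex survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the population average treatment effect from complex survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svypate)
```

## The problem

Health surveys such as NHANES reach their target population through complex
multi-stage designs: strata, clusters, oversampling of subgroups, and
nonresponse adjustments. Every record therefore carries a survey weight
$\omega_i$ — the inverse of its probability of ending up in the analysed
file. Causal-inference methods built on the potential-outcomes framework
(inverse probability of treatment weighting, G-computation,
targeted maximum likelihood estimation) address *confounding*, but as usually
applied they estimate the average treatment effect *in the sample* (SATE). If
the sample is not a simple random sample — and survey samples never are — the
sample ATE is not the *population* average treatment effect (PATE). This
package implements all three estimators with the survey weights folded in at
the right places, so the estimand is the PATE, together with the machinery
needed around them (design-robust variance, percentile and Rao–Wu–Yue
bootstrap, balance and positivity diagnostics, four regression baselines)
and a synthetic data generator with known causal truth to validate the whole
chain.

With potential outcomes $Y^{a=1}, Y^{a=0}$ and confounders $L$, the PATE is
$E[Y^{a=1} - Y^{a=0}]$ over the survey's target population. Identification
needs the usual assumptions — exchangeability given $L$, consistency,
positivity — plus correct selection modelling via the weights. Only
positivity is checkable from data; `fit_propensity()` flags fitted scores
outside a configurable $(0.001, 0.999)$ corridor, and `balance_smd()` reports
weighted standardized mean differences.

## How the weights enter each estimator

* **IPTW.** A logistic model gives $\pi_i = P(A=1 \mid L_i)$. The treatment
  weight is $t_i = 1/\pi_i$ for exposed and $1/(1-\pi_i)$ for unexposed
  units. For the PATE the analysis weight is the *product* $w_i = t_i
  \omega_i$; the estimate is the $w$-weighted difference in mean outcomes,
  computed as the exposure coefficient of a $w$-weighted linear fit so the
  design-robust sandwich variance doubles as the model-robust standard
  error.
* **G-computation.** The outcome regression $E(Y \mid A, L)$ is fitted with
  $\omega$ as probability weights; counterfactual predictions under $a=1$
  and $a=0$ are formed for every unit, and their differences are averaged
  with $\omega$ — standardisation to the *population's* confounder
  distribution. Survey weights are never multiplied into other weights here.
* **TMLE.** Starts from the same outcome model, then targets it: the clever
  covariate $H_i = A_i/\pi_i - (1-A_i)/(1-\pi_i)$ carries the exposure
  mechanism, a one-parameter fluctuation regression of $Y - \hat Q(A,L)$ on
  $H$ yields $\hat\varepsilon$, predictions update as $Q^*(a,L) = \hat
  Q(a,L) + \hat\varepsilon H(a)$, and the PATE is the $\omega$-weighted mean
  of $Q^*(1,L) - Q^*(0,L)$. The result is doubly robust: consistent if
  either the outcome model or the propensity model is correct.

Two clever-covariate placements are shipped because both appear in practice:
the default keeps $H$ plain and weights the fluctuation regression by
$\omega$; the `weight-embedded` variant multiplies $H$ by $\omega$ and
leaves the regression unweighted. The two solve the same weighted score
equation up to the weighting of the quadratic term; the plain form is
numerically stabler and is the default. The variant used is always recorded
in the result's metadata.

Whether the *propensity model itself* should be survey-weighted is genuinely
open in the applied literature. The package defaults to an unweighted
propensity fit, with $\omega$ entering only the final analysis weights, and
exposes `propensity_survey_weights = TRUE` as a switch; the choice is
recorded in each result.

## Design-based variance without the survey package

All weighted fits use probability-weighted estimating equations; variance is
the sandwich with the meat built by totalling score contributions within
PSUs and pooling their between-PSU covariance within strata (the standard
with-replacement first-stage approximation for public-release survey data).
Without design labels this reduces to the ordinary heteroscedasticity-robust
sandwich. A stratum with a single PSU is a hard error naming the stratum —
silent fixes hide design problems — with an explicit `single_psu = "center"`
opt-in that scores the lone PSU against the grand mean. Point estimates are
invariant to rescaling all weights, and with unit weights every routine
reproduces its unweighted counterpart exactly; both properties are asserted
in the test suite.

Confidence intervals for G-computation and TMLE are percentile bootstrap,
re-running the entire procedure (including the propensity fit) on every
replicate. The default scheme resamples rows, which is the common practice
for public-release extracts even though it ignores clustering; the
Rao–Wu–Yue scheme (resample $n_h - 1$ PSUs per stratum, rescale weights by
$m_{hj} n_h/(n_h-1)$) is available when stratum and PSU labels exist. A fast
influence-curve variance is offered for TMLE with the caveat that it treats
weights as fixed and ignores clustering.

## Monte Carlo counterfactuals

The G-computation literature often reports "Monte Carlo iterations" without
specifying what is simulated. Here the default `parameter-draw` mode redraws
the outcome-model coefficients from their estimated sampling distribution
(multivariate normal, design-robust covariance) each iteration and averages
the predictions; 250 iterations is the default. A deterministic `plug-in`
mode predicts at the point estimates. For a linear model and a mean
contrast the two coincide in expectation — parameter draws only add
simulation noise — so every exactness test and the acceptance checks use
plug-in mode, and parameter-draw convergence to plug-in is itself tested
(10 vs 5,000 iterations). Residual-noise simulation was considered and
rejected: for a continuous outcome and a mean contrast it cannot move the
estimate, only its Monte Carlo error. Internal seeding is wrapped so the MC
draws never perturb an enclosing bootstrap's resampling stream.

## The synthetic validation world

`generator_config()` describes a superpopulation built to exercise exactly
the failure modes survey weights address, with NHANES-like proportions:

* four confounders — age (years, uniform 8–12), sex (Bernoulli 0.51), a
  three-level group (60/25/15%), and an income-to-poverty ratio (lognormal,
  capped at 5);
* binary exposure from a logistic model on all four (defaults give ~25–30%
  prevalence, like household smoke exposure);
* continuous potential outcomes on a blood-pressure-like scale (intercept
  100, residual SD 8 mmHg), with independent Gaussian noise per potential
  outcome — only marginal means matter for ATE-type estimands;
* a treatment effect $\tau_0 + \tau_B 1[g=B] + \tau_C 1[g=C]$ (defaults
  1.5, +2, +1 mmHg), so the group is an effect modifier;
* a stratified design with the group as stratum driver, minority-like strata
  oversampled threefold (inclusion 1% vs 3%), an income-dependent selection
  tilt (log-odds 0.4 per unit of centred income ratio), and optional
  per-stratum nonresponse thinning with weights multiplied by the inverse
  response propensity.

Because the modifier strata are oversampled *and* carry larger effects, the
expected sample ATE exceeds the PATE by construction — the gap the weights
must close. Both potential outcomes are stored in the population, so
`true_estimands()` returns exact truth; `draw_survey_sample()` strips them,
so estimators can never touch them. Setting equal inclusion probabilities
and a zero selection tilt collapses the design to a simple random sample,
under which unweighted estimators become unbiased for the PATE (tested).

What the generator does *not* emulate: multi-stage cluster effects (its
pseudo-PSUs are labels without intra-cluster correlation), calibration or
raking adjustments, measurement error in the exposure, and missingness
beyond Bernoulli nonresponse. Passing tests therefore validate the
estimators' handling of unequal selection and confounding, not robustness
to every feature of real survey data.

## Validation conditions and what they showed

The replicate checks redraw the *population* each replicate, so measured
error reflects the whole pipeline rather than one finite population's noise
realisation (a fixed population's empirical g-formula value differs from its
PATE by $O(N^{-1/2})$, which resampling can never average away). Problem
sizes: superpopulations of 50,000 with samples around 1,500–2,000 and 300–500
replicates for bias and coverage; smaller bootstrap sizes (150–500) where a
check needs a bootstrap inside a replication loop. These are the package's
validation conditions, chosen once.

One empirical finding deserves emphasis: the efficiency ordering of the
three estimators depends on the outcome-model specification used in the
comparison. With the shared *additive* models that applied comparisons hold
identical across methods (this package's defaults), mean percentile-CI
widths order exactly as G-computation < TMLE < IPTW, weighted (2.65 < 2.85 <
2.88 mmHg over 24 fresh populations) and unweighted (2.17 < 2.33 < 2.34)
alike: the additive outcome model leaves the effect heterogeneity
unmodelled, and TMLE's targeting step must carry it through $1/\pi$ terms —
the same weight-multiplication that makes IPTW widest. With fully
interacted (correctly specified) outcome models the three weighted widths
collapse to within ~3% of one another and the ordering of the first two can
even invert, the targeting step then acting as a slight control variate.
The package reports measured widths rather than assuming an ordering; the
acceptance check uses the shared additive default models.

## Numerical and degenerate-input policy

Logistic fits use a quasibinomial working family (weights are probabilities,
not frequencies); (quasi-)complete separation and single-valued responses
raise explicit errors, as do propensities of exactly 0 or 1, zero total
weight in an exposure arm, non-finite fluctuation coefficients (reported
with the extreme $|H|$), and bootstrap statistics failing on more than half
the replicates. Weight truncation is off by default; an optional symmetric
quantile cap on the treatment weights reports how many were capped.
Zero-variance covariates in the balance table yield `NA`, not an error. All
randomness flows from explicit seeds; a master seed fans out to
per-estimator child seeds so a ten-estimator comparison is reproducible end
to end.

## The NHANES-style adapter

`build_analysis_dataset()` merges demographics, blood-pressure, household
smoking and income files (SAS transport or CSV) on the respondent id,
restricts to ages 8–11 with a positive MEC exam weight, averages the
available blood-pressure readings (mmHg), codes exposure as any household
smoker, categorises the income-to-poverty ratio (cutpoints 1 and 2, with an
explicit `unknown` level), and returns the dataset plus an ordered exclusion
log — eligibility first, then missing outcome, then missing exposure — whose
counts sum to the rows dropped. Variable names are configuration
(`nhanes_mapping()`), not code: public-release names change across cycles
and must be verified against the cycle's documentation. The package's test
fixtures for the adapter are synthetic six-record files built in code.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(n = 1e5, seed = 2026)
pop <- generate_population(cfg)
true_estimands(pop)$pate
samp <- draw_survey_sample(pop, cfg)
tab <- run_comparison(samp, analysis_config(B = 400, seed = 2026))
tab[, c("label", "estimate", "ci_lower", "ci_upper")]
```

The `analysis/` directory runs this end to end: `01_simulate.R` (scenario,
truth, sample), `02_compare_estimators.R` (the ten-estimator table),
`03_simulation_study.R` (bias/width/coverage summaries), `04_diagnostics.R`
(positivity, balance, weight distribution), writing all tables under
`results/`.

## Known limitations

Cross-sectional only (no time-varying confounding); linear identity-link
fluctuation for TMLE (appropriate for continuous bounded-range outcomes like
blood pressure; the bounded-logistic transform is not implemented); no
Super-Learner-style machine-learning initial estimators; no replicate-weight
(BRR/jackknife) variance; no calibration estimators; the marginal/conditional
distinction is carried as a label on every result precisely because the
comparison of adjusted regression coefficients with marginal contrasts is
meaningful only in collapsible settings.
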