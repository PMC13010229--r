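#' Reference regression baselines
#'
#' The four regression models the causal estimators are compared against:
#' unadjusted and unweighted (`naive`), survey-weighted without confounders
#' (`weights_only`), confounder-adjusted without survey weights
#' (`confounders_only`), and both (`full`). Each reports the exposure
#' coefficient of a linear fit with a design-robust Wald confidence interval.
#' All four are labelled `estimand = "conditional"`: a covariate-adjusted
#' regression coefficient holds covariates fixed, unlike the marginal
#' contrasts from IPTW / G-computation / TMLE — the two coincide only in
#' collapsible settings (linear models, no effect modification).
#'
#' @param data a `svy_data` object.
#' @param confounder_formula right-hand-side formula of adjustment terms,
#'   e.g. `~ age + sex`; default: all declared confounders, additively.
#' @param level confidence level.
#' @return Named list of four [estimate_result()]s:
#'   `naive`, `weights_only`, `confounders_only`, `full`.
#' @export
fit_reference_models <- function(data, confounder_formula = NULL,
                                 level = 0.95) {
  roles <- svy_roles(data)
  confs <- if (is.null(confounder_formula)) {
    roles$confounders
  } else {
    labels(stats::terms(confounder_formula))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)

  one <- function(adjusted, weighted, label) {
    rhs <- if (adjusted) c(roles$exposure, confs) else roles$exposure
    f <- stats::reformulate(rhs, response = roles$outcome)
    fit <- fit_weighted_glm(data, f, family = "linear",
                            weights_mode = if (weighted) "survey" else "none")
    est <- unname(stats::coef(fit)[2])
    se <- unname(sqrt(diag(fit$vcov))[2])
    estimate_result(label, est, se = se, ci_lower = est - z * se,
                    ci_upper = est + z * se, ci_method = "robust-wald",
                    weighted = weighted, adjusted = adjusted,
                    estimand = "conditional",
                    meta = list(formula = deparse(f)))
  }
  list(naive = one(FALSE, FALSE, "naive"),
       weights_only = one(FALSE, TRUE, "weights_only"),
       confounders_only = one(TRUE, FALSE, "confounders_only"),
       full = one(TRUE, TRUE, "full"))
}
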