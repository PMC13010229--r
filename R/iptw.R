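#' Fit the exposure (propensity) model
#'
#' Logistic regression of the binary exposure on the confounders. The fitted
#' propensity score \eqn{\pi_i = P(A = 1 | L_i)} summarises how likely each
#' unit was to be exposed given its covariates. Whether survey weights enter
#' this fit is a modelling choice the package records rather than hides:
#' the default fits unweighted (survey weights then enter only the final
#' analysis weights), with `use_survey_weights = TRUE` available.
#'
#' Fitted probabilities outside the positivity bounds trigger a warning: near
#' 0/1 propensities mean some covariate patterns essentially never (or always)
#' receive the exposure, and inverse weighting by them is unstable.
#'
#' @param data a `svy_data` object.
#' @param formula exposure model formula; defaults to exposure on all declared
#'   confounders. Must not involve the outcome.
#' @param use_survey_weights logical; fit the logistic model with survey
#'   weights.
#' @param positivity_bounds length-2 numeric; fitted propensities outside this
#'   open interval raise a positivity warning.
#' @return A `propensity_result`: list with `pi` (per-row scores in (0,1)),
#'   `fit` (the [fit_weighted_glm()] behind it), `survey_weighted`,
#'   `n_flagged` (count outside the bounds).
#' @export
fit_propensity <- function(data, formula = NULL, use_survey_weights = FALSE,
                           positivity_bounds = c(0.001, 0.999)) {
  roles <- svy_roles(data)
  if (is.null(formula)) {
    formula <- stats::reformulate(roles$confounders, response = roles$exposure)
  }
  if (roles$outcome %in% all.vars(formula)) {
    stop("propensity formula must not involve the outcome (", roles$outcome,
         ")", call. = FALSE)
  }
  fit <- fit_weighted_glm(data, formula, family = "logistic",
                          weights_mode = if (use_survey_weights) "survey" else "none")
  p <- fit$fitted
  n_flagged <- sum(p < positivity_bounds[1] | p > positivity_bounds[2])
  if (n_flagged > 0) {
    warning(sprintf(
      "positivity: %d fitted propensities outside (%g, %g); min %.4g, max %.4g",
      n_flagged, positivity_bounds[1], positivity_bounds[2], min(p), max(p)),
      call. = FALSE)
  }
  structure(list(pi = p, fit = fit, survey_weighted = use_survey_weights,
                 n_flagged = n_flagged, formula = formula),
            class = "propensity_result")
}

#' Combine treatment and survey weights
#'
#' The treatment weight is \eqn{1/\pi_i} for exposed and \eqn{1/(1-\pi_i)} for
#' unexposed units, reweighting the sample into a pseudo-population in which
#' measured confounders are balanced across exposure arms. Multiplying by the
#' survey weight yields the analysis weight that additionally maps the
#' pseudo-population onto the survey's target population, so the weighted
#' contrast estimates the PATE rather than the sample ATE.
#'
#' @param propensity a `propensity_result` aligned to `data`'s rows.
#' @param data a `svy_data` object.
#' @param truncation NULL (off, default) or a quantile in (0.5, 1): treatment
#'   weights are symmetrically capped at the `1 - truncation` and `truncation`
#'   quantiles of their distribution before the survey weight is applied, and
#'   the number capped is reported.
#' @param stabilized logical; use the marginal exposure prevalence as the
#'   weight numerator (stabilized weights) instead of 1.
#' @return A `combined_weights` object: list with `t` (treatment weights),
#'   `omega` (survey weights), `w = t * omega` (analysis weights),
#'   `n_capped`, `cap_quantile`.
#' @examples
#' # exposed unit with propensity 0.25 and survey weight 3: w = 4 * 3 = 12
#' @export
compute_iptw_weights <- function(propensity, data, truncation = NULL,
                                 stabilized = FALSE) {
  a <- .svy_exposure(data)
  p <- propensity$pi
  if (length(p) != length(a)) {
    stop("propensity scores not aligned to data rows", call. = FALSE)
  }
  if (any(p <= 0 | p >= 1)) {
    stop("propensity score of exactly 0 or 1: cannot form inverse weights",
         call. = FALSE)
  }
  omega <- .svy_weight(data)
  if (stabilized) {
    prev <- sum(omega * a) / sum(omega)
    t_w <- ifelse(a == 1, prev / p, (1 - prev) / (1 - p))
  } else {
    t_w <- ifelse(a == 1, 1 / p, 1 / (1 - p))
  }
  n_capped <- 0L
  if (!is.null(truncation)) {
    stopifnot(truncation > 0.5, truncation < 1)
    caps <- stats::quantile(t_w, c(1 - truncation, truncation), names = FALSE)
    n_capped <- sum(t_w < caps[1] | t_w > caps[2])
    t_w <- pmin(pmax(t_w, caps[1]), caps[2])
  }
  structure(list(t = t_w, omega = omega, w = t_w * omega,
                 n_capped = n_capped,
                 cap_quantile = if (is.null(truncation)) NA_real_ else truncation,
                 stabilized = stabilized),
            class = "combined_weights")
}

#' IPTW estimate of the population average treatment effect
#'
#' Fits the propensity model, forms combined analysis weights (treatment
#' weight times survey weight when `use_survey_weights = TRUE`), and estimates
#' the effect as the difference in analysis-weighted mean outcomes between
#' exposure arms — computed as the exposure coefficient of an analysis-weighted
#' linear regression of the outcome on the exposure, whose design-robust
#' sandwich variance supplies model-robust standard errors. With survey
#' weights excluded the same machinery targets the sample ATE instead.
#'
#' @param data a `svy_data` object.
#' @param formula propensity formula (default: exposure on all confounders).
#' @param use_survey_weights multiply treatment weights by survey weights.
#' @param propensity_survey_weights fit the propensity model itself with
#'   survey weights (see [fit_propensity()]).
#' @param truncation,stabilized passed to [compute_iptw_weights()].
#' @param ci `"robust"` (Wald from the sandwich variance, default) or
#'   `"bootstrap"` (percentile, re-running the whole procedure per replicate).
#' @param B,boot_scheme,seed bootstrap settings when `ci = "bootstrap"`.
#' @param level confidence level.
#' @return An [estimate_result()] with `method = "IPTW"`,
#'   `estimand = "marginal"`.
#' @export
estimate_iptw_pate <- function(data, formula = NULL, use_survey_weights = TRUE,
                               propensity_survey_weights = FALSE,
                               truncation = NULL, stabilized = FALSE,
                               ci = c("robust", "bootstrap"), B = 1000,
                               boot_scheme = "rows", seed = 1, level = 0.95) {
  ci <- match.arg(ci)
  roles <- svy_roles(data)

  point_fit <- function(d) {
    prop <- fit_propensity(d, formula,
                           use_survey_weights = propensity_survey_weights)
    cw <- compute_iptw_weights(prop, d, truncation = truncation,
                               stabilized = stabilized)
    w <- if (use_survey_weights) cw$w else cw$t
    a <- .svy_exposure(d)
    if (sum(w[a == 1]) <= 0 || sum(w[a == 0]) <= 0) {
      stop("an exposure arm has zero total analysis weight", call. = FALSE)
    }
    msd <- stats::reformulate(roles$exposure, response = roles$outcome)
    fit <- fit_weighted_glm(d, msd, family = "linear",
                            weights_mode = "supplied", supplied_weights = w)
    list(est = unname(stats::coef(fit)[2]),
         se = sqrt(diag(fit$vcov))[2], cw = cw)
  }

  res <- point_fit(data)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (ci == "robust") {
    lo <- res$est - z * res$se
    hi <- res$est + z * res$se
    ci_method <- "robust-wald"
    se <- res$se
  } else {
    bt <- svy_bootstrap(data, function(d) point_fit(d)$est, B = B,
                        scheme = boot_scheme, seed = seed, level = level)
    lo <- bt$ci[1]; hi <- bt$ci[2]
    se <- stats::sd(bt$replicates, na.rm = TRUE)
    ci_method <- "percentile-bootstrap"
  }
  estimate_result("IPTW", res$est, se = unname(se), ci_lower = unname(lo),
                  ci_upper = unname(hi), ci_method = ci_method,
                  weighted = use_survey_weights, adjusted = TRUE,
                  estimand = "marginal",
                  meta = list(propensity_survey_weights = propensity_survey_weights,
                              truncation = truncation, stabilized = stabilized,
                              n_capped = res$cw$n_capped, seed = seed, B = B))
}

#' Standardized mean differences before and after weighting
#'
#' Covariate balance diagnostic for the IPTW pseudo-population: for each
#' confounder (factors expanded to level indicators) the standardized mean
#' difference is the between-arm difference in means divided by the pooled
#' unweighted standard deviation. `smd_before` uses raw means, `smd_after`
#' uses `weights`-weighted means with the same (unweighted) denominator so the
#' two columns are on a common scale. |SMD| below 0.1 is the conventional
#' adequate-balance threshold.
#'
#' @param data a `svy_data` object.
#' @param weights analysis weights (e.g. `combined_weights$w` or `$t`).
#' @return data.frame with columns `covariate`, `smd_before`, `smd_after`;
#'   zero-variance covariates get NA rather than an error.
#' @export
balance_smd <- function(data, weights) {
  roles <- svy_roles(data)
  a <- .svy_exposure(data)
  stopifnot(length(weights) == nrow(data))
  cols <- list()
  for (v in roles$confounders) {
    x <- data[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- x
    } else {
      x <- as.factor(x)
      for (lev in levels(x)) {
        cols[[paste0(v, "=", lev)]] <- as.numeric(x == lev)
      }
    }
  }
  smd_one <- function(x, w) {
    s1 <- stats::sd(x[a == 1]); s0 <- stats::sd(x[a == 0])
    pooled <- sqrt((s1^2 + s0^2) / 2)
    if (!is.finite(pooled) || pooled == 0) return(c(NA_real_, NA_real_))
    before <- (mean(x[a == 1]) - mean(x[a == 0])) / pooled
    after <- (stats::weighted.mean(x[a == 1], w[a == 1]) -
                stats::weighted.mean(x[a == 0], w[a == 0])) / pooled
    c(before, after)
  }
  out <- t(vapply(cols, smd_one, numeric(2), w = weights))
  data.frame(covariate = rownames(out), smd_before = out[, 1],
             smd_after = out[, 2], row.names = NULL,
             stringsAsFactors = FALSE)
}
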