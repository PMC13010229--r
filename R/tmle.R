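# Targeted maximum likelihood estimation: start from the G-computation
# outcome model, then nudge ("target") its predictions along a clever
# covariate built from the propensity score, so the estimator solves the
# efficient influence-curve equation and is doubly robust — consistent if
# either the outcome model or the exposure model is correctly specified.

#' Clever covariate for the TMLE targeting step
#'
#' The plain variant is the signed inverse-propensity quantity
#' \eqn{H_i = A_i / \pi_i - (1 - A_i) / (1 - \pi_i)}: positive for exposed,
#' negative for unexposed rows. The weight-embedded variant multiplies the
#' plain value by the survey weight, folding the design into the covariate
#' itself (the fluctuation regression is then left unweighted); the two
#' placements solve the same weighted score equation.
#'
#' @param exposure 0/1 vector.
#' @param pi propensity scores, strictly inside (0, 1).
#' @param variant `"plain"` or `"weight-embedded"`.
#' @param omega survey weights; required for the weight-embedded variant.
#' @return A `clever_covariate` object: list with `H`, `variant`.
#' @examples
#' clever_covariate(1, 0.5)$H  #  2
#' clever_covariate(0, 0.5)$H  # -2
#' @export
clever_covariate <- function(exposure, pi,
                             variant = c("plain", "weight-embedded"),
                             omega = NULL) {
  variant <- match.arg(variant)
  if (any(pi <= 0 | pi >= 1)) {
    stop("propensity score at 0 or 1: clever covariate undefined", call. = FALSE)
  }
  H <- exposure / pi - (1 - exposure) / (1 - pi)
  if (variant == "weight-embedded") {
    if (is.null(omega)) {
      stop("weight-embedded variant needs survey weights", call. = FALSE)
    }
    H <- H * omega
  }
  structure(list(H = H, variant = variant), class = "clever_covariate")
}

#' TMLE estimate of the population average treatment effect
#'
#' Seven steps: (1) fit the initial outcome model E(Y | A, L)
#' (survey-weighted when configured) and the propensity model P(A = 1 | L);
#' (2) predict counterfactual outcomes under exposure and no exposure;
#' (3) build the clever covariate from the propensity scores; (4) estimate the
#' fluctuation coefficient by a single-parameter no-intercept regression of
#' the residual Y - Q(A, L) on H — survey-weighted in the plain variant,
#' unweighted in the weight-embedded variant, where the weights already live
#' inside H; (5) update both counterfactual predictions,
#' Q*(a, L) = Q(a, L) + eps * H(a); (6) take the survey-weighted average of
#' Q*(1, L) - Q*(0, L); (7) percentile-bootstrap the whole procedure for the
#' confidence interval (an influence-curve variance is offered as a fast
#' approximation, with the caveat that it treats the weights as fixed and
#' ignores clustering).
#'
#' @param data a `svy_data` object.
#' @param outcome_formula outcome model; default outcome ~ exposure +
#'   confounders.
#' @param propensity_formula exposure model; default exposure ~ confounders.
#' @param use_survey_weights logical; weight the outcome fit, the fluctuation
#'   (per the variant) and the final averaging by the survey weights.
#' @param variant clever-covariate placement, see [clever_covariate()].
#' @param propensity_survey_weights fit the propensity model with survey
#'   weights.
#' @param ci `"bootstrap"` (default), `"influence"` or `"none"`.
#' @param B,boot_scheme,seed,level bootstrap settings.
#' @return An [estimate_result()] with `method = "TMLE"`,
#'   `estimand = "marginal"`; `meta$epsilon` holds the fluctuation
#'   coefficient.
#' @export
tmle_pate <- function(data, outcome_formula = NULL, propensity_formula = NULL,
                      use_survey_weights = TRUE,
                      variant = c("plain", "weight-embedded"),
                      propensity_survey_weights = FALSE,
                      ci = c("bootstrap", "influence", "none"), B = 1000,
                      boot_scheme = "rows", seed = 1, level = 0.95) {
  variant <- match.arg(variant)
  ci <- match.arg(ci)
  roles <- svy_roles(data)
  if (is.null(outcome_formula)) {
    outcome_formula <- stats::reformulate(c(roles$exposure, roles$confounders),
                                          response = roles$outcome)
  }

  point_fit <- function(d) {
    y <- .svy_outcome(d)
    a <- .svy_exposure(d)
    omega <- if (use_survey_weights) .svy_weight(d) else rep(1, nrow(d))
    qfit <- fit_weighted_glm(d, outcome_formula, family = "linear",
                             weights_mode = if (use_survey_weights) "survey" else "none")
    q1 <- rowMeans(predict_counterfactuals(qfit, d, 1, mode = "plug-in")$draws)
    q0 <- rowMeans(predict_counterfactuals(qfit, d, 0, mode = "plug-in")$draws)
    qa <- ifelse(a == 1, q1, q0)
    prop <- fit_propensity(d, propensity_formula,
                           use_survey_weights = propensity_survey_weights)
    p <- prop$pi
    cc <- clever_covariate(a, p, variant = variant, omega = omega)
    H <- cc$H
    # counterfactual clever covariates under a = 1 and a = 0
    H1 <- 1 / p
    H0 <- -1 / (1 - p)
    if (variant == "weight-embedded") {
      H1 <- H1 * omega
      H0 <- H0 * omega
      fw <- rep(1, nrow(d))
    } else {
      fw <- omega
    }
    denom <- sum(fw * H^2)
    eps <- sum(fw * H * (y - qa)) / denom
    if (!is.finite(eps)) {
      stop(sprintf(
        "non-finite fluctuation coefficient; extreme clever covariate values (|H| up to %.3g)",
        max(abs(H))), call. = FALSE)
    }
    q1s <- q1 + eps * H1
    q0s <- q0 + eps * H0
    list(est = sum(omega * (q1s - q0s)) / sum(omega), eps = eps,
         ic = H * (y - ifelse(a == 1, q1s, q0s)) + (q1s - q0s),
         omega = omega)
  }

  res <- point_fit(data)
  psi <- res$est
  if (ci == "bootstrap") {
    bt <- svy_bootstrap(data, function(d) point_fit(d)$est, B = B,
                        scheme = boot_scheme, seed = seed, level = level)
    lo <- bt$ci[1]; hi <- bt$ci[2]
    se <- stats::sd(bt$replicates, na.rm = TRUE)
    ci_method <- "percentile-bootstrap"
  } else if (ci == "influence") {
    w <- res$omega
    ic <- res$ic - psi
    se <- sqrt(sum(w^2 * ic^2)) / sum(w)
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- psi - z * se; hi <- psi + z * se
    ci_method <- "influence-curve"
  } else {
    lo <- NA_real_; hi <- NA_real_; se <- NA_real_; ci_method <- "none"
  }
  estimate_result("TMLE", psi, se = unname(se), ci_lower = unname(lo),
                  ci_upper = unname(hi), ci_method = ci_method,
                  weighted = use_survey_weights, adjusted = TRUE,
                  estimand = "marginal",
                  meta = list(variant = variant, epsilon = res$eps,
                              propensity_survey_weights = propensity_survey_weights,
                              B = B, seed = seed, boot_scheme = boot_scheme))
}
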