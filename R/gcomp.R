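# G-computation (standardisation): model the outcome mechanism E(Y | A, L),
# predict each unit's outcome with exposure set to 1 and to 0, and average the
# per-unit differences over the confounder distribution — survey-weighted when
# the target is the population rather than the sample.

.with_seed <- function(seed, code) {
  # run `code` under a fixed seed without disturbing the caller's RNG stream
  # (essential inside bootstrap loops, which own the stream)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Predict counterfactual outcomes under a fixed exposure scenario
#'
#' Sets every unit's exposure to `scenario` and predicts from the fitted
#' outcome model. In `"parameter-draw"` mode the prediction is repeated over
#' Monte Carlo iterations, each drawing a coefficient vector from the model's
#' estimated sampling distribution (multivariate normal around the point
#' estimates with the fit's design-robust covariance); in `"plug-in"` mode a
#' single deterministic prediction at the point estimates is returned. Because
#' the coefficient draws are seeded, calling this for scenario 1 and scenario
#' 0 with the same `seed` uses identical draws, so their difference isolates
#' the exposure contrast.
#'
#' @param model a `weighted_fit` for the outcome.
#' @param data data whose confounder columns feed the prediction.
#' @param scenario 0 or 1: the exposure value imposed on everyone.
#' @param mode `"parameter-draw"` or `"plug-in"`.
#' @param n_mc Monte Carlo iterations (>= 1); forced to 1 in plug-in mode.
#' @param seed seed for the coefficient draws.
#' @return A `counterfactual_draws` object: list with `draws` (rows x
#'   iterations matrix of predicted outcomes), `scenario`, `mode`, `n_mc`,
#'   `seed`.
#' @export
predict_counterfactuals <- function(model, data, scenario,
                                    mode = c("parameter-draw", "plug-in"),
                                    n_mc = 250, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(scenario %in% c(0, 1))
  if (n_mc < 1) stop("n_mc must be >= 1", call. = FALSE)
  exposure <- all.vars(model$formula)[2] # first RHS variable by convention
  # identify the exposure column name from the data roles when available
  if (inherits(data, "svy_data")) exposure <- svy_roles(data)$exposure
  nd <- as.data.frame(data)
  nd[[exposure]] <- scenario
  X <- stats::model.matrix(stats::delete.response(stats::terms(model$formula)),
                           nd)
  if (mode == "plug-in") {
    draws <- matrix(as.numeric(X %*% model$coefficients), ncol = 1)
    n_mc <- 1L
  } else {
    betas <- .with_seed(seed, .rmvnorm(n_mc, model$coefficients, model$vcov))
    draws <- X %*% t(betas)
  }
  structure(list(draws = draws, scenario = scenario, mode = mode,
                 n_mc = n_mc, seed = seed),
            class = "counterfactual_draws")
}

# multivariate normal draws via eigen decomposition (tolerates PSD matrices)
.rmvnorm <- function(n, mean, sigma) {
  k <- length(mean)
  e <- eigen(sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  R <- e$vectors %*% (t(e$vectors) * sqrt(ev))
  z <- matrix(stats::rnorm(n * k), n, k)
  sweep(z %*% R, 2, mean, "+")
}

#' G-computation estimate of the population average treatment effect
#'
#' Fits the outcome regression E(Y | A, L) — survey-weighted when
#' `use_survey_weights = TRUE` so the outcome mechanism reflects the design —
#' predicts every unit's outcome under exposure and under no exposure (over
#' `n_mc` Monte Carlo iterations in parameter-draw mode), averages the
#' per-unit differences over iterations, and finally takes the survey-weighted
#' average over units so the confounder distribution being standardised to is
#' the population's, not the sample's. The confidence interval is a percentile
#' bootstrap that re-runs the entire procedure on each replicate.
#'
#' @param data a `svy_data` object.
#' @param formula outcome formula; must include the exposure term. Default:
#'   outcome on exposure plus all confounders, additively.
#' @param use_survey_weights logical; weight both the outcome fit and the
#'   final averaging by the survey weights.
#' @param mode,n_mc Monte Carlo settings, see [predict_counterfactuals()].
#' @param ci `"bootstrap"` (percentile, default) or `"none"`.
#' @param B bootstrap replicates.
#' @param boot_scheme `"rows"` or `"rao_wu_yue"`.
#' @param seed master seed (drives both the MC draws and the bootstrap).
#' @param level confidence level.
#' @return An [estimate_result()] with `method = "G-computation"`,
#'   `estimand = "marginal"`.
#' @export
gcomp_pate <- function(data, formula = NULL, use_survey_weights = TRUE,
                       mode = c("parameter-draw", "plug-in"), n_mc = 250,
                       ci = c("bootstrap", "none"), B = 1000,
                       boot_scheme = "rows", seed = 1, level = 0.95) {
  mode <- match.arg(mode)
  ci <- match.arg(ci)
  roles <- svy_roles(data)
  if (is.null(formula)) {
    formula <- stats::reformulate(c(roles$exposure, roles$confounders),
                                  response = roles$outcome)
  }
  if (!(roles$exposure %in% all.vars(formula))) {
    stop("outcome formula must include the exposure term ", roles$exposure,
         call. = FALSE)
  }

  point_fit <- function(d) {
    fit <- fit_weighted_glm(d, formula, family = "linear",
                            weights_mode = if (use_survey_weights) "survey" else "none")
    d1 <- predict_counterfactuals(fit, d, 1, mode = mode, n_mc = n_mc,
                                  seed = seed)
    d0 <- predict_counterfactuals(fit, d, 0, mode = mode, n_mc = n_mc,
                                  seed = seed)
    effect <- rowMeans(d1$draws) - rowMeans(d0$draws)
    w <- if (use_survey_weights) .svy_weight(d) else rep(1, nrow(d))
    sum(w * effect) / sum(w)
  }

  est <- point_fit(data)
  if (ci == "bootstrap") {
    bt <- svy_bootstrap(data, point_fit, B = B, scheme = boot_scheme,
                        seed = seed, level = level)
    lo <- bt$ci[1]; hi <- bt$ci[2]
    se <- stats::sd(bt$replicates, na.rm = TRUE)
    ci_method <- "percentile-bootstrap"
  } else {
    lo <- NA_real_; hi <- NA_real_; se <- NA_real_; ci_method <- "none"
  }
  estimate_result("G-computation", est, se = se, ci_lower = unname(lo),
                  ci_upper = unname(hi), ci_method = ci_method,
                  weighted = use_survey_weights, adjusted = TRUE,
                  estimand = "marginal",
                  meta = list(mode = mode, n_mc = n_mc, B = B, seed = seed,
                              boot_scheme = boot_scheme))
}
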