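#' Configuration for the synthetic survey-data generator
#'
#' Describes a superpopulation of children-like units with four confounders
#' (age and an income-to-poverty ratio, both continuous; sex and a three-level
#' ethnicity-like group, categorical), a binary exposure assigned by a logistic
#' model on the confounders, continuous potential outcomes on a blood-pressure
#' scale, and a stratified sampling design whose inclusion probabilities can
#' differ by stratum (oversampling) and depend on a covariate (informative
#' selection). The group variable drives both effect modification and the
#' sampling strata, so the sample-average and population-average treatment
#' effects separate by design.
#'
#' Linear predictors use centred continuous covariates: `age - 10` and
#' `pir - 1.5`. Coefficient vectors are ordered
#' `(intercept, age, sex, groupB, groupC, pir)`.
#'
#' @param n superpopulation size (>= 2).
#' @param exposure_coefs logistic coefficients for P(A = 1 | L).
#' @param outcome_coefs linear coefficients for the systematic part of the
#'   untreated potential outcome (outcome units, e.g. mmHg).
#' @param tau0 baseline treatment effect (outcome units).
#' @param tau_mod length-2 vector: additional effect in groups B and C
#'   (effect-measure modification).
#' @param noise_sd standard deviation of the Gaussian outcome noise;
#'   independent draws for the two potential outcomes.
#' @param group_probs population frequencies of groups A, B, C.
#' @param inclusion_prob named per-stratum inclusion probabilities in (0, 1];
#'   strata are the group levels. Unequal values oversample, NHANES-style.
#' @param selection_coef log-odds shift of selection per unit of centred
#'   `pir`; 0 disables covariate-dependent (informative-beyond-stratum)
#'   selection.
#' @param response_prob optional named per-stratum response probabilities in
#'   (0, 1]; nonresponse is a second Bernoulli thinning and survey weights are
#'   multiplied by the inverse response propensity.
#' @param sampling `"poisson"` (independent Bernoulli selection, default) or
#'   `"stratified"` (fixed-size simple random sample per stratum; requires
#'   `selection_coef = 0`).
#' @param n_psu_per_stratum if > 0, units are clustered into this many
#'   pseudo-PSUs per stratum so design-based variance and the Rao-Wu-Yue
#'   bootstrap can be exercised.
#' @param seed integer; fully determines the generated population.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n = 1e5,
                             exposure_coefs = c(-1.4, 0.10, 0.25, 0.9, 0.5, -0.30),
                             outcome_coefs = c(100, 1.2, 1.0, 2.0, 1.0, -1.5),
                             tau0 = 1.5,
                             tau_mod = c(B = 2.0, C = 1.0),
                             noise_sd = 8,
                             group_probs = c(A = 0.60, B = 0.25, C = 0.15),
                             inclusion_prob = c(A = 0.010, B = 0.030, C = 0.030),
                             selection_coef = 0.4,
                             response_prob = NULL,
                             sampling = c("poisson", "stratified"),
                             n_psu_per_stratum = 0,
                             seed = 1) {
  sampling <- match.arg(sampling)
  if (!is.numeric(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  if (length(exposure_coefs) != 6 || length(outcome_coefs) != 6) {
    stop("coefficient vectors must have length 6 ",
         "(intercept, age, sex, groupB, groupC, pir)", call. = FALSE)
  }
  if (length(tau_mod) != 2) stop("tau_mod must have length 2 (B, C)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (abs(sum(group_probs) - 1) > 1e-8 || any(group_probs <= 0)) {
    stop("group_probs must be positive and sum to 1", call. = FALSE)
  }
  if (any(inclusion_prob <= 0) || any(inclusion_prob > 1)) {
    stop("inclusion probabilities must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(response_prob) &&
      (any(response_prob <= 0) || any(response_prob > 1))) {
    stop("response probabilities must lie in (0, 1]", call. = FALSE)
  }
  if (sampling == "stratified" && selection_coef != 0) {
    stop("fixed-size stratified sampling requires selection_coef = 0",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), exposure_coefs = exposure_coefs,
                 outcome_coefs = outcome_coefs, tau0 = tau0,
                 tau_mod = tau_mod, noise_sd = noise_sd,
                 group_probs = group_probs, inclusion_prob = inclusion_prob,
                 selection_coef = selection_coef,
                 response_prob = response_prob, sampling = sampling,
                 n_psu_per_stratum = as.integer(n_psu_per_stratum),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Read / write a generator configuration as YAML
#' @param config a `generator_config`.
#' @param path file path.
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  # named vectors serialize as YAML maps only as lists
  for (f in c("group_probs", "inclusion_prob", "tau_mod", "response_prob")) {
    if (!is.null(x[[f]])) x[[f]] <- as.list(x[[f]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("group_probs", "inclusion_prob", "tau_mod", "response_prob")) {
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  }
  do.call(generator_config, x)
}

# covariate expansion shared by the exposure and outcome linear predictors
.gen_design <- function(df) {
  cbind(1, df$age - 10, df$sex,
        as.numeric(df$group == "B"), as.numeric(df$group == "C"),
        df$pir - 1.5)
}

#' Generate a synthetic superpopulation with known causal truth
#'
#' Draws confounders, assigns the exposure from the configured logistic model,
#' builds both potential outcomes (so exact estimand truth is computable), and
#' attaches stratum labels and selection probabilities for the sampling step.
#' The observed outcome obeys consistency, `Y = A*y1 + (1-A)*y0`, row by row.
#'
#' @param config a [generator_config()].
#' @return A `population` data.frame with columns `id`, `age`, `sex`, `group`,
#'   `pir`, `A`, `y0`, `y1`, `Y`, `stratum`, `psu`, `p_sel`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n
  df <- data.frame(
    id = seq_len(n),
    age = stats::runif(n, 8, 12),
    sex = stats::rbinom(n, 1, 0.51),
    group = factor(sample(names(config$group_probs), n, replace = TRUE,
                          prob = config$group_probs), levels = c("A", "B", "C")),
    pir = pmin(stats::rlnorm(n, meanlog = 0.3, sdlog = 0.6), 5)
  )
  X <- .gen_design(df)
  pi_a <- stats::plogis(as.numeric(X %*% config$exposure_coefs))
  df$A <- stats::rbinom(n, 1, pi_a)
  sys0 <- as.numeric(X %*% config$outcome_coefs)
  tau <- config$tau0 + config$tau_mod[1] * (df$group == "B") +
    config$tau_mod[2] * (df$group == "C")
  df$y0 <- sys0 + stats::rnorm(n, 0, config$noise_sd)
  df$y1 <- sys0 + tau + stats::rnorm(n, 0, config$noise_sd)
  df$Y <- df$A * df$y1 + (1 - df$A) * df$y0
  df$stratum <- as.character(df$group)
  df$psu <- if (config$n_psu_per_stratum > 0) {
    paste0(df$stratum, "-",
           sample.int(config$n_psu_per_stratum, n, replace = TRUE))
  } else NA_character_
  base <- config$inclusion_prob[df$stratum]
  if (anyNA(base)) {
    stop("inclusion_prob missing for stratum ",
         paste(unique(df$stratum[is.na(base)]), collapse = ", "), call. = FALSE)
  }
  df$p_sel <- stats::plogis(stats::qlogis(as.numeric(base)) +
                              config$selection_coef * (df$pir - 1.5))
  class(df) <- c("population", "data.frame")
  attr(df, "config") <- config
  df
}

#' Draw an informative survey sample from a population
#'
#' Selects units according to the configured design, applies optional
#' nonresponse thinning, and returns a [survey_dataset()] whose weight column
#' is the inverse of the realized selection probability (times the inverse
#' response propensity when nonresponse is enabled). Potential-outcome and
#' selection-probability columns are stripped: the analyst sees observed data
#' only, the causal truth stays with the population.
#'
#' @param population a `population` from [generate_population()].
#' @param config the same [generator_config()] (for the sampling design).
#' @param seed seed for the selection draw; defaults to `config$seed + 1` so a
#'   config alone pins down one population-plus-sample realization. Pass
#'   different seeds for replicate samples from a fixed population.
#' @return A `svy_data` object with confounders `age`, `sex`, `group`, `pir`.
#' @export
draw_survey_sample <- function(population, config, seed = config$seed + 1L) {
  stopifnot(inherits(population, "population"), nrow(population) > 0)
  set.seed(seed)
  if (config$sampling == "poisson") {
    keep <- stats::runif(nrow(population)) < population$p_sel
    samp <- population[keep, , drop = FALSE]
    samp$w <- 1 / samp$p_sel
  } else {
    parts <- split(population, population$stratum)
    parts <- lapply(parts, function(ph) {
      p <- config$inclusion_prob[ph$stratum[1]]
      if (is.na(p)) stop("inclusion_prob missing for stratum ", ph$stratum[1],
                         call. = FALSE)
      nh <- max(1L, round(p * nrow(ph)))
      out <- ph[sample.int(nrow(ph), nh), , drop = FALSE]
      out$w <- nrow(ph) / nh
      out
    })
    samp <- do.call(rbind, parts)
    rownames(samp) <- NULL
  }
  if (nrow(samp) == 0) {
    stop("degenerate sample: no units selected; raise inclusion probabilities",
         call. = FALSE)
  }
  if (!is.null(config$response_prob)) {
    rp <- config$response_prob[samp$stratum]
    if (anyNA(rp)) {
      stop("response_prob missing for stratum ",
           paste(unique(samp$stratum[is.na(rp)]), collapse = ", "),
           call. = FALSE)
    }
    respond <- stats::runif(nrow(samp)) < rp
    samp <- samp[respond, , drop = FALSE]
    if (nrow(samp) == 0) {
      stop("degenerate sample: all selected units nonrespondents", call. = FALSE)
    }
    samp$w <- samp$w / config$response_prob[samp$stratum]
  }
  keep_cols <- c("id", "age", "sex", "group", "pir", "A", "Y", "stratum",
                 "psu", "w")
  samp <- as.data.frame(samp)[, keep_cols]
  has_psu <- !anyNA(samp$psu)
  survey_dataset(samp, outcome = "Y", exposure = "A", weight = "w",
                 confounders = c("age", "sex", "group", "pir"),
                 strata = "stratum", psu = if (has_psu) "psu" else NULL)
}

#' Exact causal estimands of a synthetic population
#'
#' Computes the population average treatment effect (PATE, the mean of
#' `y1 - y0` over all units), the PATE among the exposed (PATT), and — when a
#' config is supplied — the expected sample ATE (`sate_expected`): the mean
#' over replicate survey draws of the average unit-level effect among sampled
#' units. Under informative sampling with effect modification the expected
#' sample ATE differs from the PATE, which is exactly the gap survey weights
#' exist to close.
#'
#' @param population a `population` carrying both potential outcomes.
#' @param config optional [generator_config()]; needed for `sate_expected`.
#' @param sate_replicates number of replicate sample draws.
#' @return list with `pate`, `patt`, `sate_expected` (NA without a config).
#' @export
true_estimands <- function(population, config = NULL, sate_replicates = 200) {
  if (!all(c("y1", "y0") %in% names(population))) {
    stop("population lacks potential-outcome columns y1/y0", call. = FALSE)
  }
  delta <- population$y1 - population$y0
  pate <- mean(delta)
  patt <- mean(delta[population$A == 1])
  sate_expected <- NA_real_
  if (!is.null(config)) {
    # average the realized sample ATE over replicate informative draws
    sates <- vapply(seq_len(sate_replicates), function(r) {
      set.seed(config$seed + 1000L + r)
      if (config$sampling == "poisson") {
        keep <- stats::runif(nrow(population)) < population$p_sel
      } else {
        keep <- rep(FALSE, nrow(population))
        for (st in unique(population$stratum)) {
          idx <- which(population$stratum == st)
          nh <- max(1L, round(config$inclusion_prob[st] * length(idx)))
          keep[sample(idx, nh)] <- TRUE
        }
      }
      mean(delta[keep])
    }, numeric(1))
    sate_expected <- mean(sates)
  }
  list(pate = pate, patt = patt, sate_expected = sate_expected)
}
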