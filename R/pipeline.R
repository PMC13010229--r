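# Orchestration: the ten-estimator comparison (four regression baselines plus
# IPTW / G-computation / TMLE, each with and without survey weights) and the
# replicate simulation study that measures bias, efficiency and CI coverage
# against the generator's known truth.

#' Analysis configuration for the estimator comparison
#'
#' @param B bootstrap replicates for G-computation and TMLE intervals.
#' @param n_mc Monte Carlo iterations for G-computation counterfactuals.
#' @param gcomp_mode `"parameter-draw"` or `"plug-in"`.
#' @param tmle_variant clever-covariate placement, see [clever_covariate()].
#' @param tmle_ci `"bootstrap"` or `"influence"`.
#' @param iptw_ci `"robust"` or `"bootstrap"`.
#' @param boot_scheme `"rows"` or `"rao_wu_yue"`.
#' @param propensity_survey_weights fit propensity models with survey weights.
#' @param seed master seed; per-estimator child seeds are derived from it so
#'   the full comparison is reproducible end to end.
#' @param level confidence level.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(B = 1000, n_mc = 250,
                            gcomp_mode = "parameter-draw",
                            tmle_variant = "plain", tmle_ci = "bootstrap",
                            iptw_ci = "robust", boot_scheme = "rows",
                            propensity_survey_weights = FALSE, seed = 1,
                            level = 0.95) {
  structure(list(B = B, n_mc = n_mc, gcomp_mode = gcomp_mode,
                 tmle_variant = tmle_variant, tmle_ci = tmle_ci,
                 iptw_ci = iptw_ci, boot_scheme = boot_scheme,
                 propensity_survey_weights = propensity_survey_weights,
                 seed = as.integer(seed), level = level),
            class = "analysis_config")
}

# deterministic fan-out of one master seed into k child seeds
.child_seeds <- function(master, k) {
  .with_seed(master, sample.int(.Machine$integer.max - 1L, k))
}

#' Run the full ten-estimator comparison
#'
#' Produces the standard comparison layout: four reference regressions
#' (naive; survey weights only; confounders only; both), then IPTW,
#' G-computation and TMLE each without and with survey weights — ten rows in
#' a fixed order. Exposure and outcome model specifications are shared across
#' methods so differences reflect the estimators, not the models. One
#' estimator failing is recorded in its row's `error` column without
#' aborting the rest.
#'
#' @param data a `svy_data` object, or a [generator_config()] (a population is
#'   generated and one survey sample drawn from it).
#' @param config an [analysis_config()].
#' @return data.frame of class `comparison_table` with one row per estimator
#'   (`label`, `method`, `weighted`, `adjusted`, `estimand`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`, `ci_method`, `error`), forest-plot ready.
#' @export
run_comparison <- function(data, config = analysis_config()) {
  if (inherits(data, "generator_config")) {
    pop <- generate_population(data)
    data <- draw_survey_sample(pop, data)
  }
  stopifnot(inherits(data, "svy_data"), inherits(config, "analysis_config"))
  seeds <- .child_seeds(config$seed, 10L)
  labels <- c("naive", "weights_only", "confounders_only", "full",
              "iptw_unweighted", "iptw_weighted",
              "gcomp_unweighted", "gcomp_weighted",
              "tmle_unweighted", "tmle_weighted")
  run <- function(expr) tryCatch(expr, error = function(e) conditionMessage(e))
  refs <- run(fit_reference_models(data, level = config$level))
  results <- vector("list", 10)
  if (is.list(refs)) {
    results[1:4] <- refs
  } else {
    results[1:4] <- rep(list(refs), 4)
  }
  iptw_one <- function(weighted, s) {
    estimate_iptw_pate(data, use_survey_weights = weighted,
                       propensity_survey_weights = config$propensity_survey_weights,
                       ci = config$iptw_ci, B = config$B,
                       boot_scheme = config$boot_scheme, seed = s,
                       level = config$level)
  }
  gcomp_one <- function(weighted, s) {
    gcomp_pate(data, use_survey_weights = weighted, mode = config$gcomp_mode,
               n_mc = config$n_mc, ci = "bootstrap", B = config$B,
               boot_scheme = config$boot_scheme, seed = s,
               level = config$level)
  }
  tmle_one <- function(weighted, s) {
    tmle_pate(data, use_survey_weights = weighted,
              variant = config$tmle_variant,
              propensity_survey_weights = config$propensity_survey_weights,
              ci = config$tmle_ci, B = config$B,
              boot_scheme = config$boot_scheme, seed = s,
              level = config$level)
  }
  results[[5]] <- run(iptw_one(FALSE, seeds[5]))
  results[[6]] <- run(iptw_one(TRUE, seeds[6]))
  results[[7]] <- run(gcomp_one(FALSE, seeds[7]))
  results[[8]] <- run(gcomp_one(TRUE, seeds[8]))
  results[[9]] <- run(tmle_one(FALSE, seeds[9]))
  results[[10]] <- run(tmle_one(TRUE, seeds[10]))
  out <- .results_table(results, labels)
  class(out) <- c("comparison_table", "data.frame")
  attr(out, "config") <- config
  out
}

#' Replicate simulation study of the ten estimators
#'
#' Generates one superpopulation from `gen_config`, computes the exact PATE
#' from its stored potential outcomes, then draws `n_replicates` survey
#' samples and runs the comparison on each, summarising per-estimator bias,
#' Monte Carlo (empirical) SE, mean CI width and 95% CI coverage of the true
#' PATE. Bootstrap sizes come from `config$B`; keep them modest here, each
#' replicate re-runs every bootstrap.
#'
#' @param gen_config a [generator_config()].
#' @param n_replicates number of replicate samples (>= 2).
#' @param config an [analysis_config()].
#' @param estimators optional character vector restricting the comparison to a
#'   subset of the ten labels.
#' @return list with `summary` (one row per estimator: `label`,
#'   `mean_estimate`, `bias`, `mc_se_of_mean`, `empirical_se`,
#'   `mean_ci_width`, `coverage`), `truth` (from [true_estimands()]),
#'   `estimates` (replicates x estimators matrix) and CI arrays.
#' @export
simulation_study <- function(gen_config, n_replicates, config = analysis_config(),
                             estimators = NULL) {
  stopifnot(n_replicates >= 2)
  pop <- generate_population(gen_config)
  truth <- true_estimands(pop, gen_config, sate_replicates = 100)
  labels <- c("naive", "weights_only", "confounders_only", "full",
              "iptw_unweighted", "iptw_weighted",
              "gcomp_unweighted", "gcomp_weighted",
              "tmle_unweighted", "tmle_weighted")
  if (is.null(estimators)) estimators <- labels
  stopifnot(all(estimators %in% labels))
  k <- length(estimators)
  est <- lo <- hi <- matrix(NA_real_, n_replicates, k,
                            dimnames = list(NULL, estimators))
  rep_seeds <- .child_seeds(config$seed, n_replicates)
  for (r in seq_len(n_replicates)) {
    samp <- draw_survey_sample(pop, gen_config, seed = rep_seeds[r])
    cfg_r <- config
    cfg_r$seed <- rep_seeds[r]
    tab <- suppressWarnings(run_comparison(samp, cfg_r))
    rows <- match(estimators, tab$label)
    est[r, ] <- tab$estimate[rows]
    lo[r, ] <- tab$ci_lower[rows]
    hi[r, ] <- tab$ci_upper[rows]
  }
  pate <- truth$pate
  summ <- data.frame(
    label = estimators,
    mean_estimate = colMeans(est, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - pate,
    mc_se_of_mean = apply(est, 2, stats::sd, na.rm = TRUE) /
      sqrt(colSums(!is.na(est))),
    empirical_se = apply(est, 2, stats::sd, na.rm = TRUE),
    mean_ci_width = colMeans(hi - lo, na.rm = TRUE),
    coverage = colMeans(lo <= pate & pate <= hi, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summ, truth = truth, estimates = est,
       ci_lower = lo, ci_upper = hi, n_replicates = n_replicates)
}

#' Export a comparison table for forest plotting
#'
#' @param table a `comparison_table` from [run_comparison()].
#' @param path output path; `.csv` or `.json` by extension.
#' @export
write_comparison <- function(table, path) {
  if (grepl("\\.json$", path)) {
    writeLines(.simple_json(table), path)
  } else {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  }
  invisible(path)
}

# minimal row-wise JSON serialiser for the comparison table
.simple_json <- function(df) {
  fmt <- function(v) {
    if (is.na(v)) return("null")
    if (is.numeric(v)) return(format(v, digits = 10))
    if (is.logical(v)) return(if (v) "true" else "false")
    paste0('"', gsub('"', '\\\\"', as.character(v)), '"')
  }
  rows <- vapply(seq_len(nrow(df)), function(i) {
    fields <- vapply(names(df), function(nm) {
      paste0('"', nm, '": ', fmt(df[[nm]][i]))
    }, character(1))
    paste0("  {", paste(fields, collapse = ", "), "}")
  }, character(1))
  paste0("[\n", paste(rows, collapse = ",\n"), "\n]")
}
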