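# Propensity model, combined weights, IPTW point estimation and balance
# diagnostics.

test_that("intercept-only propensity equals the sample prevalence", {
  set.seed(8)
  n <- 5000
  df <- data.frame(Y = rnorm(n), A = rbinom(n, 1, 0.3), x = rnorm(n), w = 1)
  d <- survey_dataset(df, confounders = "x")
  prop <- fit_propensity(d, A ~ 1)
  expect_equal(unique(round(prop$pi, 10)), round(mean(df$A), 10))
})

test_that("saturated propensity recovers level-specific exposure rates", {
  df <- data.frame(
    A = rep(c(1, 0, 1, 0), c(20, 80, 60, 40)),
    g = rep(c(0, 0, 1, 1), c(20, 80, 60, 40)),
    Y = 0, w = 1
  )
  d <- survey_dataset(df, confounders = "g")
  prop <- fit_propensity(d, A ~ factor(g))
  expect_equal(sort(unique(round(prop$pi, 8))), c(0.2, 0.6))
})

test_that("all-exposed input raises a separation error", {
  df <- data.frame(Y = rnorm(20), A = 1, x = rnorm(20), w = 1)
  d <- survey_dataset(df, confounders = "x")
  expect_error(fit_propensity(d), "separation")
})

test_that("the propensity formula may not involve the outcome", {
  d <- make_small_survey()
  expect_error(fit_propensity(d, A ~ Y + x), "outcome")
})

test_that("treatment and analysis weights follow the inverse-propensity product rule", {
  df <- data.frame(Y = 0, A = c(1, 0, 1), w = c(1, 1, 3), x = 0)
  d <- survey_dataset(df, confounders = "x")
  prop <- structure(list(pi = c(0.5, 0.5, 0.25)), class = "propensity_result")
  cw <- compute_iptw_weights(prop, d)
  expect_equal(cw$t, c(2, 2, 4))
  expect_equal(cw$w, c(2, 2, 12)) # survey weight multiplies the last row to 4*3
  expect_equal(cw$n_capped, 0L)
  prop_bad <- structure(list(pi = c(1, 0.5, 0.25)), class = "propensity_result")
  expect_error(compute_iptw_weights(prop_bad, d), "0 or 1")
})

test_that("truncation caps extreme treatment weights and reports the count", {
  set.seed(3)
  n <- 400
  x <- rnorm(n)
  a <- rbinom(n, 1, plogis(2 * x))
  d <- survey_dataset(data.frame(Y = rnorm(n), A = a, x = x, w = 1),
                      confounders = "x")
  prop <- suppressWarnings(fit_propensity(d))
  cw <- compute_iptw_weights(prop, d, truncation = 0.95)
  expect_gt(cw$n_capped, 0)
  expect_lte(max(cw$t), quantile(1 / ifelse(a == 1, prop$pi, 1 - prop$pi), 0.95))
})

test_that("inverse-propensity weights rebuild the pseudo-population size", {
  set.seed(12)
  n <- 20000
  x <- rnorm(n)
  a <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  d <- survey_dataset(data.frame(Y = rnorm(n), A = a, x = x, w = 1),
                      confounders = "x")
  cw <- compute_iptw_weights(fit_propensity(d), d)
  # E[A / pi] = 1, so the exposed arm's treatment weights sum to about n
  expect_lt(abs(sum(cw$t[a == 1]) - n) / n, 0.05)
  expect_lt(abs(sum(cw$t[a == 0]) - n) / n, 0.05)
})

test_that("with constant propensity and unit weights IPTW is the raw mean difference", {
  d <- make_small_survey(n = 300, seed = 4)
  est <- estimate_iptw_pate(d, formula = A ~ 1, use_survey_weights = FALSE)
  raw <- mean(d$Y[d$A == 1]) - mean(d$Y[d$A == 0])
  expect_equal(est$estimate, raw)
  expect_identical(est$estimand, "marginal")
  expect_true(est$ci_lower < est$estimate & est$estimate < est$ci_upper)
})

test_that("IPTW on the discrete toy equals brute-force standardization", {
  d <- make_toy_discrete()
  oracle <- brute_force_standardization(d)
  est <- estimate_iptw_pate(d, formula = A ~ factor(l),
                            use_survey_weights = TRUE,
                            propensity_survey_weights = TRUE)
  expect_equal(est$estimate, oracle, tolerance = 1e-6)
})

test_that("unbiased for zero effect under informative sampling with weights", {
  # a fresh population per replicate, so the error measured is the whole
  # design-plus-estimation pipeline's, not one finite population's noise
  errs <- vapply(1:150, function(r) {
    cfg <- generator_config(n = 2e4, tau0 = 0, tau_mod = c(B = 0, C = 0),
                            seed = 1000 + r)
    pop <- generate_population(cfg)
    s <- draw_survey_sample(pop, cfg)
    estimate_iptw_pate(s, use_survey_weights = TRUE)$estimate -
      true_estimands(pop)$pate
  }, numeric(1))
  mc_se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 3 * mc_se)
})

test_that("standardized mean differences follow the formula and shrink after weighting", {
  # means 1 vs 2 with pooled SD forced to 2 -> SMD 0.5
  set.seed(1)
  x <- c(1 + 2 * scale(rnorm(50))[, 1], 2 + 2 * scale(rnorm(50))[, 1])
  df <- data.frame(Y = 0, A = rep(c(0, 1), each = 50), x = x, w = 1,
                   z = 1) # z has zero variance
  d <- survey_dataset(df, confounders = c("x", "z"))
  sm <- balance_smd(d, weights = rep(1, 100))
  expect_equal(sm$smd_before[sm$covariate == "x"], 0.5, tolerance = 1e-10)
  expect_true(is.na(sm$smd_before[sm$covariate == "z"]))

  # after IPTW weighting on a well-specified model, covariates balance
  set.seed(19)
  n <- 2000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  a <- rbinom(n, 1, plogis(-0.3 + 0.9 * x1 + 0.7 * x2))
  dd <- survey_dataset(data.frame(Y = rnorm(n), A = a, x1 = x1, x2 = x2, w = 1),
                       confounders = c("x1", "x2"))
  cw <- compute_iptw_weights(fit_propensity(dd), dd)
  sm2 <- balance_smd(dd, weights = cw$t)
  expect_gt(max(abs(sm2$smd_before)), 0.1) # confounded before weighting
  expect_lt(max(abs(sm2$smd_after)), 0.1)  # conventional balance threshold
})
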