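# Weighted means, weighted GLMs with design-robust variance, and the
# bootstrap machinery.

test_that("weighted mean follows the direct formula", {
  expect_equal(weighted_mean_se(c(1, 3), c(1, 1))$mean, 2)
  expect_equal(weighted_mean_se(c(0, 10), c(1, 4))$mean, 8)
  expect_error(weighted_mean_se(1:3, c(1, -1, 1)), "positive")
})

test_that("stratified linearization SE matches the hand-expanded formula", {
  # 3 strata x 2 single-row PSUs: with n_h = 2 the stratum contribution
  # collapses to (z_h1 - z_h2)^2 for linearized residuals z
  x <- c(1, 4, 2, 9, 5, 3)
  w <- c(1, 2, 1.5, 1, 3, 2)
  s <- rep(1:3, each = 2)
  res <- weighted_mean_se(x, w, strata = s, psus = 1:6)
  mu <- sum(w * x) / sum(w)
  z <- w * (x - mu) / sum(w)
  v_hand <- sum(tapply(seq_along(z), s, function(i) (z[i[1]] - z[i[2]])^2))
  expect_equal(res$mean, mu)
  expect_equal(res$se, sqrt(v_hand))
})

test_that("a stratum with a single PSU errors by name, with a center opt-in", {
  x <- c(1, 2, 3); w <- rep(1, 3)
  expect_error(weighted_mean_se(x, w, strata = c("s1", "s1", "s2"),
                                psus = c(1, 2, 3)),
               "'s2'")
  res <- weighted_mean_se(x, w, strata = c("s1", "s1", "s2"),
                          psus = c(1, 2, 3), single_psu = "center")
  expect_true(is.finite(res$se))
})

test_that("unweighted linear fit on balanced data recovers the group-mean difference", {
  d <- make_small_survey(n = 100)
  fit <- fit_weighted_glm(d, Y ~ A, family = "linear", weights_mode = "none")
  diff_means <- mean(d$Y[d$A == 1]) - mean(d$Y[d$A == 0])
  expect_equal(unname(coef(fit)[2]), diff_means)
})

test_that("logistic fit on a 2x2 table reproduces the closed-form log odds ratio", {
  # cell counts: exposed-by-group a=20, b=30, c=10, d=40
  df <- data.frame(
    A = rep(c(1, 1, 0, 0), c(20, 30, 10, 40)),
    g = rep(c(1, 0, 1, 0), c(20, 30, 10, 40)),
    Y = 0, w = 1
  )
  d <- survey_dataset(df, outcome = "Y", exposure = "A", weight = "w",
                      confounders = "g")
  fit <- fit_weighted_glm(d, A ~ g, family = "logistic")
  expect_equal(unname(coef(fit)[2]), log((20 * 40) / (30 * 10)),
               tolerance = 1e-6)
})

test_that("coefficients are invariant to rescaling all weights", {
  d <- make_small_survey(n = 150, equal_weights = FALSE)
  f1 <- fit_weighted_glm(d, Y ~ A + x, weights_mode = "survey")
  d7 <- as.data.frame(d)
  d7$w <- d7$w * 7
  d7 <- survey_dataset(d7, outcome = "Y", exposure = "A", weight = "w",
                       confounders = "x")
  f7 <- fit_weighted_glm(d7, Y ~ A + x, weights_mode = "survey")
  expect_equal(coef(f1), coef(f7))
  expect_equal(vcov(f1), vcov(f7), tolerance = 1e-9)
})

test_that("with equal weights the weighted fit reproduces the unweighted one", {
  d <- make_small_survey(n = 120, equal_weights = TRUE)
  f_none <- fit_weighted_glm(d, Y ~ A + x, weights_mode = "none")
  f_svy <- fit_weighted_glm(d, Y ~ A + x, weights_mode = "survey")
  expect_equal(coef(f_none), coef(f_svy))
  expect_equal(unname(coef(f_none)), unname(coef(lm(Y ~ A + x, data = d))))
})

test_that("sandwich variance is symmetric with nonnegative diagonal", {
  d <- make_small_survey(n = 80, equal_weights = FALSE)
  fit <- fit_weighted_glm(d, Y ~ A + x, weights_mode = "survey")
  expect_equal(vcov(fit), t(vcov(fit)))
  expect_true(all(diag(vcov(fit)) >= 0))
})

test_that("degenerate logistic inputs raise a separation error", {
  df <- data.frame(Y = 0, A = 1, x = rnorm(30), w = 1)
  d <- survey_dataset(df, outcome = "Y", exposure = "A", weight = "w")
  expect_error(fit_weighted_glm(d, A ~ x, family = "logistic"), "separation")
})

test_that("bootstrap of a constant statistic gives a degenerate CI", {
  d <- make_small_survey(n = 40)
  bt <- svy_bootstrap(d, function(dd) 5, B = 20, seed = 1)
  expect_equal(unname(bt$ci), c(5, 5))
})

test_that("rows-scheme bootstrap matches an independent resampling loop replicate-for-replicate", {
  d <- make_small_survey(n = 60, equal_weights = FALSE)
  stat <- function(dd) weighted.mean(dd$Y, dd$w)
  B <- 200
  bt <- svy_bootstrap(d, stat, B = B, scheme = "rows", seed = 123)
  # oracle: same seed protocol, coded independently of svy_bootstrap
  set.seed(123)
  df <- as.data.frame(d)
  oracle <- vapply(seq_len(B), function(b) {
    idx <- sample.int(nrow(df), nrow(df), replace = TRUE)
    weighted.mean(df$Y[idx], df$w[idx])
  }, numeric(1))
  expect_equal(as.numeric(bt$replicates), oracle)
  expect_equal(unname(bt$ci), unname(quantile(oracle, c(.025, .975),
                                              names = FALSE)))
})

test_that("Rao-Wu-Yue bootstrap resamples PSUs with rescaled weights", {
  cfg <- generator_config(n = 2e4, n_psu_per_stratum = 8, seed = 31)
  s <- draw_survey_sample(generate_population(cfg), cfg)
  stat <- function(dd) weighted.mean(dd$Y, dd$w)
  bt <- svy_bootstrap(s, stat, B = 100, scheme = "rao_wu_yue", seed = 5)
  expect_equal(bt$n_failed, 0)
  expect_true(bt$ci[1] < bt$point && bt$point < bt$ci[2])
  # total weight is preserved in expectation: replicate means stay near point
  expect_lt(abs(mean(bt$replicates) - bt$point), 4 * sd(bt$replicates))
  # singleton-PSU stratum is a hard error
  d2 <- survey_dataset(
    data.frame(Y = rnorm(12), A = rep(0:1, 6), w = 1,
               stratum = rep(c("s1", "s2"), c(8, 4)),
               psu = c(rep(c("p1", "p2"), 4), rep("p3", 4))),
    outcome = "Y", exposure = "A", weight = "w",
    strata = "stratum", psu = "psu")
  expect_error(svy_bootstrap(d2, stat, B = 5, scheme = "rao_wu_yue", seed = 1),
               "single PSU")
})

test_that("bootstrap aborts with a diagnostic when the statistic mostly fails", {
  d <- make_small_survey(n = 30)
  flaky <- function(dd) stop("boom")
  expect_error(svy_bootstrap(d, flaky, B = 10, seed = 1), "boom")
})
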