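# Synthetic superpopulation generator: reproducibility, consistency,
# known-truth estimands, and the sampling design.

test_that("identical config and seed give bit-identical population and sample", {
  cfg <- generator_config(n = 5000, seed = 42)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1, p2)
  s1 <- draw_survey_sample(p1, cfg)
  s2 <- draw_survey_sample(p2, cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("consistency identity Y = A*y1 + (1-A)*y0 holds row-wise", {
  pop <- generate_population(generator_config(n = 3000, seed = 7))
  expect_equal(pop$Y, pop$A * pop$y1 + (1 - pop$A) * pop$y0)
  expect_true(all(pop$p_sel > 0 & pop$p_sel <= 1))
})

test_that("null and constant treatment effects give exact PATE truth", {
  cfg0 <- generator_config(n = 4000, tau0 = 0, tau_mod = c(B = 0, C = 0),
                           seed = 5)
  tr0 <- true_estimands(generate_population(cfg0))
  expect_equal(tr0$pate, 0, tolerance = 0.3) # y1-y0 has independent noise
  cfg2 <- generator_config(n = 4000, tau0 = 2, tau_mod = c(B = 0, C = 0),
                           noise_sd = 0, seed = 5)
  tr2 <- true_estimands(generate_population(cfg2))
  expect_equal(tr2$pate, 2)
  expect_equal(tr2$patt, 2)
  expect_identical(class(tr2$sate_expected), "numeric") # NA without a config
})

test_that("effect modification on a half-prevalent modifier gives PATE of 1.5", {
  # groups B and C jointly play a Bernoulli(0.5) effect modifier adding +1
  cfg <- generator_config(n = 1e5, tau0 = 1,
                          group_probs = c(A = 0.5, B = 0.4, C = 0.1),
                          tau_mod = c(B = 1, C = 1), seed = 9)
  tr <- true_estimands(generate_population(cfg))
  # analytic expectation E(1 + modifier) = 1.5; Monte-Carlo error at N = 1e5
  mc_se <- sqrt(2 * cfg$noise_sd^2 + 0.25) / sqrt(1e5)
  expect_lt(abs(tr$pate - 1.5), 4 * mc_se)
})

test_that("survey weights are the inverse inclusion probabilities", {
  cfg <- generator_config(n = 5000, inclusion_prob = c(A = .1, B = .1, C = .1),
                          selection_coef = 0, seed = 3)
  s <- draw_survey_sample(generate_population(cfg), cfg)
  expect_true(all(abs(s$w - 10) < 1e-12))
  cfg2 <- generator_config(n = 5000, inclusion_prob = c(A = .5, B = .1, C = .1),
                           selection_coef = 0, seed = 3)
  s2 <- draw_survey_sample(generate_population(cfg2), cfg2)
  expect_true(all(abs(s2$w[s2$stratum == "A"] - 2) < 1e-12))
  expect_true(all(abs(s2$w[s2$stratum != "A"] - 10) < 1e-12))
})

test_that("nonresponse thinning multiplies weights by inverse response propensity", {
  cfg <- generator_config(n = 8000, inclusion_prob = c(A = .2, B = .2, C = .2),
                          selection_coef = 0,
                          response_prob = c(A = 1, B = 0.5, C = 1), seed = 4)
  s <- draw_survey_sample(generate_population(cfg), cfg)
  expect_true(all(abs(s$w[s$stratum == "B"] - 10) < 1e-12)) # 5 * (1 / 0.5)
  expect_true(all(abs(s$w[s$stratum != "B"] - 5) < 1e-12))
})

test_that("Horvitz-Thompson weighted mean is unbiased over replicate draws", {
  cfg <- generator_config(n = 5000, seed = 21) # informative design
  pop <- generate_population(cfg)
  ht <- vapply(1:1000, function(r) {
    s <- draw_survey_sample(pop, cfg, seed = 10000 + r)
    sum(s$w * s$Y) / nrow(pop)
  }, numeric(1))
  mc_se <- sd(ht) / sqrt(length(ht))
  expect_lt(abs(mean(ht) - mean(pop$Y)), 3 * mc_se)
})

test_that("PATT exceeds PATE when the modifier is more prevalent among exposed", {
  # brute-force check on a hand-built 100-unit population: modifier m adds
  # +2 to the unit effect and is overrepresented among the exposed
  m <- rep(c(1, 0), c(40, 60))
  a <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 50))
  y0 <- rep(5, 100)
  y1 <- y0 + 1 + 2 * m
  pop <- data.frame(id = 1:100, A = a, y0 = y0, y1 = y1,
                    Y = a * y1 + (1 - a) * y0)
  class(pop) <- c("population", "data.frame")
  tr <- true_estimands(pop)
  expect_equal(tr$pate, mean(y1 - y0))
  expect_equal(tr$patt, mean((y1 - y0)[a == 1]))
  expect_gt(tr$patt, tr$pate)
})

test_that("oversampling the high-effect strata separates expected SATE from PATE", {
  cfg <- generator_config(n = 4e4, seed = 13) # B/C oversampled, tau_mod > 0
  pop <- generate_population(cfg)
  tr <- true_estimands(pop, cfg, sate_replicates = 100)
  expect_false(is.na(tr$sate_expected))
  # modifier groups are oversampled and carry larger effects: SATE > PATE
  expect_gt(tr$sate_expected, tr$pate)
})

test_that("non-informative design collapses to equal weights and matching means", {
  cfg <- noninformative_config(n = 2e4, seed = 17)
  s <- draw_survey_sample(generate_population(cfg), cfg)
  expect_equal(weighted.mean(s$Y, s$w), mean(s$Y))
  expect_equal(weighted.mean(s$age, s$w), mean(s$age))
})

test_that("potential outcomes are stripped from the survey sample", {
  cfg <- generator_config(n = 3000, seed = 2)
  s <- draw_survey_sample(generate_population(cfg), cfg)
  expect_false(any(c("y0", "y1", "p_sel") %in% names(s)))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n = 1), "n must be")
  expect_error(generator_config(inclusion_prob = c(A = 0, B = .1, C = .1)),
               "inclusion probabilities")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(sampling = "stratified", selection_coef = 0.3),
               "selection_coef")
  cfg <- generator_config(n = 1000,
                          inclusion_prob = c(A = 1e-5, B = 1e-5, C = 1e-5),
                          selection_coef = 0, seed = 1)
  pop <- generate_population(cfg)
  expect_error(draw_survey_sample(pop, cfg, seed = 2), "degenerate sample")
  expect_error(true_estimands(data.frame(Y = 1:3)), "potential-outcome")
})

test_that("generator config round-trips through YAML", {
  cfg <- generator_config(n = 1234, tau0 = 0.7, seed = 99,
                          response_prob = c(A = .9, B = .8, C = 1))
  path <- tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_equal(cfg2$n, cfg$n)
  expect_equal(cfg2$tau0, cfg$tau0)
  expect_equal(cfg2$inclusion_prob, cfg$inclusion_prob)
  expect_identical(generate_population(cfg2), generate_population(cfg))
})
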