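# Fixtures shared across test files. Everything is built in code; no stored
# data.

# Hand-built discrete dataset: one binary confounder `l`, all cell sizes and
# outcome values fixed, plus deterministic (non-constant) survey weights.
# Saturated models on this dataset are nonparametric, so IPTW, plug-in
# G-computation and TMLE must all reproduce the brute-force standardisation.
make_toy_discrete <- function(constant_weights = FALSE) {
  cells <- list( # l, A, n, outcome level
    list(l = 0, A = 1, n = 20, m = 10),
    list(l = 0, A = 0, n = 30, m = 8),
    list(l = 1, A = 1, n = 10, m = 14),
    list(l = 1, A = 0, n = 40, m = 9)
  )
  rows <- do.call(rbind, lapply(cells, function(cc) {
    # deterministic within-cell spread around the cell level
    dev <- seq(-1, 1, length.out = cc$n)
    data.frame(l = cc$l, A = cc$A, Y = cc$m + dev)
  }))
  rows$w <- if (constant_weights) rep(1, nrow(rows)) else
    0.5 + (seq_len(nrow(rows)) %% 4)
  survey_dataset(rows, outcome = "Y", exposure = "A", weight = "w",
                 confounders = "l")
}

# Independent oracle: nonparametric (g-formula) standardisation over the
# weighted confounder distribution, straight from cell means.
brute_force_standardization <- function(data) {
  df <- as.data.frame(data)
  w <- df$w
  total <- sum(w)
  out <- 0
  for (lv in unique(df$l)) {
    in_l <- df$l == lv
    p_l <- sum(w[in_l]) / total
    m1 <- weighted.mean(df$Y[in_l & df$A == 1], w[in_l & df$A == 1])
    m0 <- weighted.mean(df$Y[in_l & df$A == 0], w[in_l & df$A == 0])
    out <- out + p_l * (m1 - m0)
  }
  out
}

# Small survey dataset with balanced arms and a continuous confounder, for
# quick regression identities.
make_small_survey <- function(n = 200, seed = 11, equal_weights = TRUE) {
  set.seed(seed)
  x <- rnorm(n)
  a <- rep(c(0, 1), length.out = n)
  y <- 1 + 2 * a + 0.5 * x + rnorm(n)
  w <- if (equal_weights) rep(1, n) else runif(n, 0.5, 4)
  survey_dataset(data.frame(Y = y, A = a, x = x, w = w),
                 outcome = "Y", exposure = "A", weight = "w",
                 confounders = "x")
}

# Generator config for a non-informative design: equal inclusion
# probabilities, no covariate-dependent selection, so the sample is a simple
# random (Poisson) sample and unweighted estimators are unbiased for the PATE.
noninformative_config <- function(n = 2e4, p = 0.1, seed = 1, ...) {
  generator_config(n = n,
                   inclusion_prob = c(A = p, B = p, C = p),
                   selection_coef = 0, seed = seed, ...)
}

# Synthetic NHANES-style component files (written to a tempdir) mirroring the
# public-release layout: 6 fabricated records, 2 outside the age range, 1
# with no blood-pressure readings.
write_synthetic_nhanes <- function(dir = tempdir()) {
  demo <- data.frame(
    SEQN = 1:6,
    RIDAGEYR = c(9, 10, 5, 14, 8, 11),   # records 3 and 4 ineligible
    RIAGENDR = c(1, 2, 1, 2, 2, 1),
    RIDRETH3 = c(1, 3, 3, 4, 6, 3),
    WTMECPRP = c(12000, 9000, 8000, 7000, 15000, 11000),
    SDMVSTRA = c(171, 171, 172, 172, 173, 173),
    SDMVPSU = c(1, 2, 1, 2, 1, 2)
  )
  bp <- data.frame(
    SEQN = 1:6,
    BPXOSY1 = c(98, 104, 99, 101, NA, 95),
    BPXOSY2 = c(102, 106, 97, 99, NA, 97),
    BPXOSY3 = c(NA, 105, 98, 100, NA, 96),
    BPXODI1 = c(60, 64, 58, 61, NA, 55),
    BPXODI2 = c(62, 66, 56, 59, NA, 57),
    BPXODI3 = c(NA, 65, 57, 60, NA, 56)
  )
  smoke <- data.frame(SEQN = 1:6, SMD460 = c(0, 1, 0, 2, 1, 0))
  income <- data.frame(SEQN = 1:6,
                       INDFMPIR = c(0.8, 1.5, 2.2, 3.1, 0.4, NA))
  paths <- list(
    demographics = file.path(dir, "synthetic_demo.csv"),
    bp = file.path(dir, "synthetic_bpx.csv"),
    smoking = file.path(dir, "synthetic_smq.csv"),
    income = file.path(dir, "synthetic_inc.csv")
  )
  write.csv(demo, paths$demographics, row.names = FALSE)
  write.csv(bp, paths$bp, row.names = FALSE)
  write.csv(smoke, paths$smoking, row.names = FALSE)
  write.csv(income, paths$income, row.names = FALSE)
  paths
}
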