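#' Survey-weighted mean with linearization standard error
#'
#' Point estimate is the Hajek (ratio) estimator \eqn{\sum w_i x_i / \sum w_i}.
#' The standard error uses first-stage with-replacement Taylor linearization:
#' linearized residuals are totalled within PSUs and their between-PSU variance
#' is accumulated within strata. When no stratum/PSU labels are given each row
#' is treated as a PSU in a single stratum, which reduces to the usual robust
#' (sandwich) variance of a weighted mean.
#'
#' @param values numeric vector.
#' @param weights positive survey weights, same length.
#' @param strata,psus optional design labels, same length.
#' @param single_psu what to do with a stratum containing a single PSU:
#'   `"fail"` (default) raises an error naming the stratum, `"center"` scores
#'   the lone PSU against the grand mean of all PSU totals.
#' @return list with components `mean` and `se`.
#' @examples
#' weighted_mean_se(c(0, 10), c(1, 4))$mean # 8
#' @export
weighted_mean_se <- function(values, weights, strata = NULL, psus = NULL,
                             single_psu = c("fail", "center")) {
  single_psu <- match.arg(single_psu)
  n <- length(values)
  stopifnot(length(weights) == n)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  sw <- sum(weights)
  if (sw <= 0) stop("total weight is zero", call. = FALSE)
  m <- sum(weights * values) / sw
  # linearized contribution of each row to the ratio estimator
  z <- weights * (values - m) / sw
  list(mean = m,
       se = sqrt(drop(.linearized_variance(z, strata, psus, single_psu))))
}

# Between-PSU within-stratum variance of a total whose per-row linearized
# contributions are the rows of `z` (vector or matrix). With no labels, rows
# act as PSUs of a single stratum.
.linearized_variance <- function(z, strata = NULL, psus = NULL,
                                 single_psu = "fail") {
  z <- as.matrix(z)
  n <- nrow(z)
  if (is.null(strata)) strata <- rep(1L, n)
  if (is.null(psus)) psus <- seq_len(n)
  strata <- as.character(strata)
  psus <- paste(strata, as.character(psus), sep = "\r") # PSU ids nest in strata
  # PSU totals
  zt <- rowsum(z, group = psus, reorder = FALSE)
  psu_str <- strata[!duplicated(psus)]
  V <- matrix(0, ncol(z), ncol(z))
  grand <- colMeans(zt)
  for (h in unique(psu_str)) {
    rows <- zt[psu_str == h, , drop = FALSE]
    nh <- nrow(rows)
    if (nh == 1L) {
      if (single_psu == "fail") {
        stop("stratum '", sub("\r.*$", "", h),
             "' has a single PSU; design variance undefined ",
             "(use single_psu = \"center\" to score it against the grand mean)",
             call. = FALSE)
      }
      dev <- sweep(rows, 2, grand)
      V <- V + crossprod(dev)
      next
    }
    dev <- sweep(rows, 2, colMeans(rows))
    V <- V + nh / (nh - 1) * crossprod(dev)
  }
  V
}

#' Fit a survey-weighted generalized linear model
#'
#' Linear or logistic regression with survey weights used as probability
#' weights (weighted estimating equations), and a design-robust sandwich
#' variance: score contributions are totalled within PSUs and their
#' between-PSU covariance accumulated within strata. With no design labels the
#' variance is the ordinary heteroscedasticity-robust sandwich. Coefficients
#' are invariant to rescaling all weights by a positive constant.
#'
#' @param data a `svy_data` object from [survey_dataset()].
#' @param formula model formula over columns of `data`.
#' @param family `"linear"` (identity link, Gaussian working model) or
#'   `"logistic"` (logit link, binomial working model).
#' @param weights_mode `"none"` (all weights 1), `"survey"` (the dataset's
#'   survey weights) or `"supplied"` (the `supplied_weights` vector, e.g.
#'   combined treatment-by-survey analysis weights).
#' @param supplied_weights numeric vector of positive weights, required when
#'   `weights_mode = "supplied"`.
#' @param single_psu passed to the variance engine; see [weighted_mean_se()].
#' @return A `weighted_fit` object: list with `coefficients`, `vcov`
#'   (design-robust), `fitted`, `weights`, `family`, `formula`, `converged`,
#'   `model_matrix`, and the underlying `fit`.
#' @export
fit_weighted_glm <- function(data, formula, family = c("linear", "logistic"),
                             weights_mode = c("none", "survey", "supplied"),
                             supplied_weights = NULL,
                             single_psu = c("fail", "center")) {
  family <- match.arg(family)
  weights_mode <- match.arg(weights_mode)
  single_psu <- match.arg(single_psu)
  df <- as.data.frame(data)
  n <- nrow(df)
  w <- switch(weights_mode,
              none = rep(1, n),
              survey = .svy_weight(data),
              supplied = {
                if (is.null(supplied_weights) || length(supplied_weights) != n)
                  stop("supplied_weights must match the number of rows",
                       call. = FALSE)
                supplied_weights
              })
  if (any(w <= 0)) stop("analysis weights must be positive", call. = FALSE)
  df$.w <- w
  yname <- all.vars(formula)[1]
  y <- stats::model.response(stats::model.frame(formula, df))

  if (family == "logistic") {
    if (length(unique(y)) < 2L) {
      stop("perfect separation: the response takes a single value; ",
           "the exposure model cannot be fitted", call. = FALSE)
    }
    fit <- stats::glm(formula, data = df, weights = .w,
                      family = stats::quasibinomial())
    if (!fit$converged) {
      stop("logistic fit did not converge after ", fit$iter, " iterations",
           call. = FALSE)
    }
    mu <- fit$fitted.values
    eps <- 1e-8
    if (any(mu < eps | mu > 1 - eps)) {
      # fitted probabilities pinned at 0/1 signal (quasi-)complete separation
      cls <- split(fit$linear.predictors, y)
      if (length(cls) == 2L && max(cls[[1]]) < min(cls[[2]])) {
        stop("perfect separation detected in logistic fit; ",
             "review the covariate set", call. = FALSE)
      }
    }
  } else {
    fit <- stats::lm(formula, data = df, weights = .w)
    if (anyNA(stats::coef(fit))) {
      stop("singular design matrix: ", paste(
        names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
        " not estimable", call. = FALSE)
    }
    mu <- fit$fitted.values
  }

  X <- stats::model.matrix(formula, df)
  resid <- y - mu
  # bread: derivative of the weighted estimating equations
  info <- if (family == "logistic") {
    crossprod(X, X * (w * mu * (1 - mu)))
  } else {
    crossprod(X, X * w)
  }
  bread <- solve(info)
  scores <- X * (w * resid)                      # per-row estimating scores
  meat <- .linearized_variance(scores, .svy_strata(data), .svy_psu(data),
                               single_psu)
  vc <- bread %*% meat %*% bread
  vc <- (vc + t(vc)) / 2                          # enforce symmetry

  structure(list(coefficients = stats::coef(fit), vcov = vc,
                 fitted = as.numeric(mu), weights = w, family = family,
                 formula = formula, converged = TRUE,
                 model_matrix = X, fit = fit,
                 weights_mode = weights_mode),
            class = "weighted_fit")
}

#' @export
coef.weighted_fit <- function(object, ...) object$coefficients

#' @export
vcov.weighted_fit <- function(object, ...) object$vcov

#' @export
print.weighted_fit <- function(x, ...) {
  cat(sprintf("Weighted %s fit (%s weights), design-robust SEs\n",
              x$family, x$weights_mode))
  se <- sqrt(diag(x$vcov))
  print(cbind(Estimate = x$coefficients, `Robust SE` = se))
  invisible(x)
}

#' Predict from a weighted fit on new data
#'
#' @param object a `weighted_fit`.
#' @param newdata data.frame with the model's covariates.
#' @param type `"response"` or `"link"`.
#' @param ... unused.
#' @export
predict.weighted_fit <- function(object, newdata,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- as.numeric(stats::model.matrix(stats::delete.response(
    stats::terms(object$formula)), newdata) %*% object$coefficients)
  if (object$family == "logistic" && type == "response") stats::plogis(eta)
  else eta
}

#' Bootstrap a survey statistic with percentile confidence interval
#'
#' Two resampling schemes: `"rows"` resamples records with replacement (the
#' default, matching the common practice for public-release survey extracts),
#' and `"rao_wu_yue"` resamples \eqn{n_h - 1} PSUs with replacement within each
#' stratum and rescales the survey weights by \eqn{m_{hj} n_h / (n_h - 1)}
#' (with \eqn{m_{hj}} the number of times PSU \eqn{j} was drawn), preserving
#' the clustered, stratified design.
#'
#' @param data a `svy_data` object.
#' @param statistic function taking a `svy_data` and returning a numeric
#'   scalar or vector.
#' @param B number of bootstrap replicates (>= 1).
#' @param scheme `"rows"` or `"rao_wu_yue"`.
#' @param seed integer seed; the replicate stream is fully reproducible.
#' @param level confidence level for the percentile interval.
#' @return A `svy_boot` object: list with `replicates` (B x k matrix), `ci`
#'   (2 x k, percentile), `point` (statistic on the original data), `level`,
#'   `n_failed`, `scheme`.
#' @export
svy_bootstrap <- function(data, statistic, B = 1000,
                          scheme = c("rows", "rao_wu_yue"), seed = 1,
                          level = 0.95) {
  scheme <- match.arg(scheme)
  stopifnot(B >= 1)
  n <- nrow(data)
  point <- statistic(data)
  k <- length(point)
  wname <- svy_roles(data)$weight

  if (scheme == "rao_wu_yue") {
    strata <- .svy_strata(data)
    psus <- .svy_psu(data)
    if (is.null(strata) || is.null(psus)) {
      stop("rao_wu_yue scheme requires stratum and PSU labels", call. = FALSE)
    }
    strata <- as.character(strata)
    psu_id <- paste(strata, as.character(psus), sep = "\r")
    psu_tab <- !duplicated(psu_id)
    psu_by_str <- split(psu_id[psu_tab], strata[psu_tab])
    if (any(vapply(psu_by_str, length, 1L) < 2L)) {
      bad <- names(psu_by_str)[vapply(psu_by_str, length, 1L) < 2L]
      stop("rao_wu_yue: stratum ", paste(bad, collapse = ", "),
           " has a single PSU; cannot resample", call. = FALSE)
    }
    row_by_psu <- split(seq_len(n), psu_id)
  }

  set.seed(seed)
  reps <- matrix(NA_real_, B, k)
  failures <- character(0)
  for (b in seq_len(B)) {
    rep_data <- if (scheme == "rows") {
      idx <- sample.int(n, n, replace = TRUE)
      .svy_rewrap(as.data.frame(data)[idx, , drop = FALSE], data)
    } else {
      pieces <- vector("list", length(psu_by_str))
      for (s in seq_along(psu_by_str)) {
        ids <- psu_by_str[[s]]
        nh <- length(ids)
        draw <- sample(ids, nh - 1L, replace = TRUE)
        m <- table(factor(draw, levels = ids))
        keep <- ids[m > 0]
        rows <- unlist(row_by_psu[keep], use.names = FALSE)
        piece <- as.data.frame(data)[rows, , drop = FALSE]
        mult <- as.numeric(m[psu_id[rows]]) * nh / (nh - 1)
        piece[[wname]] <- piece[[wname]] * mult
        pieces[[s]] <- piece
      }
      .svy_rewrap(do.call(rbind, pieces), data)
    }
    val <- tryCatch(statistic(rep_data), error = function(e) e)
    if (inherits(val, "error")) {
      failures <- c(failures, conditionMessage(val))
    } else {
      reps[b, ] <- val
    }
  }
  n_failed <- length(failures)
  if (n_failed > B / 2) {
    stop("bootstrap aborted: statistic failed on ", n_failed, "/", B,
         " replicates; first error: ", failures[1], call. = FALSE)
  }
  ok <- stats::complete.cases(reps)
  alpha <- (1 - level) / 2
  ci <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  if (k == 1L) ci <- as.numeric(ci)
  structure(list(replicates = reps, ci = ci, point = point, level = level,
                 n_failed = n_failed, scheme = scheme, seed = seed),
            class = "svy_boot")
}

#' @export
print.svy_boot <- function(x, ...) {
  cat(sprintf("Bootstrap (%s scheme, B=%d, %d failed)\n",
              x$scheme, nrow(x$replicates), x$n_failed))
  cat("point:", signif(x$point, 5), "\n")
  cat(sprintf("%g%% percentile CI: [%s]\n", 100 * x$level,
              paste(signif(x$ci, 5), collapse = ", ")))
  invisible(x)
}
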