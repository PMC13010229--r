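#' Labelled effect-estimate container
#'
#' Every estimator in the package returns one of these so downstream tables
#' carry the metadata needed to compare like with like — in particular whether
#' the estimate is marginal (IPTW, G-computation, TMLE: the average outcome
#' difference if everyone vs no one were exposed) or conditional (regression
#' coefficients holding covariates fixed). The two coincide only in
#' collapsible settings such as linear models without effect modification.
#'
#' @param method method label (e.g. "IPTW", "G-computation", "TMLE", "naive").
#' @param estimate point estimate in outcome units.
#' @param se standard error (NA when only a percentile CI is available).
#' @param ci_lower,ci_upper confidence limits.
#' @param ci_method how the CI was built (e.g. "robust-wald",
#'   "percentile-bootstrap").
#' @param weighted logical: were survey weights used?
#' @param adjusted logical: was confounding adjusted for?
#' @param estimand "marginal" or "conditional".
#' @param meta named list of run metadata (seed, B, n_mc, variant, ...).
#' @return An `estimate_result` object.
#' @export
estimate_result <- function(method, estimate, se = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            ci_method = NA_character_, weighted = FALSE,
                            adjusted = TRUE,
                            estimand = c("marginal", "conditional"),
                            meta = list()) {
  estimand <- match.arg(estimand)
  if (is.finite(ci_lower) && is.finite(ci_upper) && is.finite(estimate)) {
    if (ci_lower > estimate + 1e-8 || ci_upper < estimate - 1e-8) {
      stop("estimate_result: CI does not bracket the point estimate",
           call. = FALSE)
    }
  }
  structure(list(method = method, estimate = estimate, se = se,
                 ci_lower = ci_lower, ci_upper = ci_upper,
                 ci_method = ci_method, weighted = isTRUE(weighted),
                 adjusted = isTRUE(adjusted), estimand = estimand,
                 meta = meta),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("%s (%s, %s, %s): %.3f", x$method, x$estimand,
              if (x$weighted) "survey-weighted" else "unweighted",
              if (x$adjusted) "adjusted" else "unadjusted", x$estimate))
  if (is.finite(x$ci_lower)) {
    cat(sprintf("  95%% CI [%.3f, %.3f] (%s)", x$ci_lower, x$ci_upper,
                x$ci_method))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.estimate_result <- function(x, ...) {
  data.frame(method = x$method, weighted = x$weighted, adjusted = x$adjusted,
             estimand = x$estimand, estimate = x$estimate, se = x$se,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper,
             ci_method = x$ci_method, stringsAsFactors = FALSE)
}

# bind a list of estimate_results (or error placeholders) into one table
.results_table <- function(results, labels) {
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (inherits(r, "estimate_result")) {
      cbind(label = labels[i], as.data.frame(r), error = NA_character_)
    } else {
      data.frame(label = labels[i], method = NA, weighted = NA, adjusted = NA,
                 estimand = NA, estimate = NA_real_, se = NA_real_,
                 ci_lower = NA_real_, ci_upper = NA_real_, ci_method = NA,
                 error = as.character(r), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
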