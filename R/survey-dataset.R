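#' Construct a survey analysis dataset
#'
#' Bundles a data frame of sampled units with the column roles every estimator
#' in the package needs: a continuous outcome, a binary exposure, a positive
#' survey weight, and (optionally) stratum and primary sampling unit (PSU)
#' labels for design-based variance. The survey weight is the inverse
#' probability of selection into the sample, adjusted for nonresponse, so
#' weighted statistics estimate finite-population quantities.
#'
#' @param data data.frame with one row per sampled unit.
#' @param outcome name of the continuous outcome column (e.g. systolic blood
#'   pressure in mmHg).
#' @param exposure name of the binary (0/1) exposure column.
#' @param weight name of the survey-weight column; all values must be positive.
#'   Use a column of ones for a self-weighting (simple random) sample.
#' @param confounders character vector of confounder column names. Defaults to
#'   every remaining column that is not a design variable.
#' @param strata,psu optional names of the stratum and PSU label columns. When
#'   both are present each PSU must belong to exactly one stratum.
#' @return An object of class `svy_data`: the validated data.frame with the
#'   column roles stored as attributes (retrieved with [svy_roles()]).
#' @examples
#' d <- data.frame(Y = rnorm(10), A = rbinom(10, 1, 0.5), w = runif(10, 1, 3),
#'                 x = rnorm(10))
#' sd <- survey_dataset(d, outcome = "Y", exposure = "A", weight = "w")
#' svy_roles(sd)$confounders
#' @export
survey_dataset <- function(data, outcome = "Y", exposure = "A", weight = "w",
                           confounders = NULL, strata = NULL, psu = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  needed <- c(outcome, exposure, weight, strata, psu)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("survey_dataset: columns not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  y <- data[[outcome]]
  a <- data[[exposure]]
  w <- data[[weight]]
  if (anyNA(y) || anyNA(a) || anyNA(w)) {
    stop("survey_dataset: missing values in outcome, exposure or weight; ",
         "apply a complete-case filter first", call. = FALSE)
  }
  if (!all(a %in% c(0, 1))) {
    stop("survey_dataset: exposure must be coded 0/1", call. = FALSE)
  }
  if (!is.numeric(w) || any(w <= 0)) {
    stop("survey_dataset: survey weights must be strictly positive", call. = FALSE)
  }
  if (!is.null(psu) && is.null(strata)) {
    # PSUs without strata: treat the whole sample as one stratum
    strata_chk <- rep(1L, nrow(data))
  } else if (!is.null(psu)) {
    strata_chk <- data[[strata]]
  }
  if (!is.null(psu)) {
    tab <- unique(data.frame(psu = data[[psu]], stratum = strata_chk))
    if (anyDuplicated(tab$psu)) {
      stop("survey_dataset: a PSU label maps to more than one stratum",
           call. = FALSE)
    }
  }
  if (is.null(confounders)) {
    confounders <- setdiff(names(data), c(outcome, exposure, weight, strata, psu))
  }
  structure(data,
            class = c("svy_data", "data.frame"),
            svy_roles = list(outcome = outcome, exposure = exposure,
                             weight = weight, confounders = confounders,
                             strata = strata, psu = psu))
}

#' Column roles of a survey dataset
#'
#' @param data a `svy_data` object from [survey_dataset()].
#' @return Named list with elements `outcome`, `exposure`, `weight`,
#'   `confounders`, `strata`, `psu`.
#' @export
svy_roles <- function(data) {
  r <- attr(data, "svy_roles")
  if (is.null(r)) stop("not a survey_dataset; see ?survey_dataset", call. = FALSE)
  r
}

# internal accessors ---------------------------------------------------------

.svy_outcome <- function(data) data[[svy_roles(data)$outcome]]
.svy_exposure <- function(data) data[[svy_roles(data)$exposure]]
.svy_weight <- function(data) data[[svy_roles(data)$weight]]
.svy_strata <- function(data) {
  s <- svy_roles(data)$strata
  if (is.null(s)) NULL else data[[s]]
}
.svy_psu <- function(data) {
  s <- svy_roles(data)$psu
  if (is.null(s)) NULL else data[[s]]
}

# re-wrap a plain data.frame (e.g. a bootstrap resample) with the same roles
.svy_rewrap <- function(df, template) {
  structure(as.data.frame(df),
            class = c("svy_data", "data.frame"),
            svy_roles = attr(template, "svy_roles"))
}

#' @export
print.svy_data <- function(x, ...) {
  r <- attr(x, "svy_roles")
  cat(sprintf("Survey dataset: %d units | outcome=%s exposure=%s weight=%s\n",
              nrow(x), r$outcome, r$exposure, r$weight))
  if (!is.null(r$strata) || !is.null(r$psu)) {
    cat(sprintf("  design: strata=%s psu=%s\n",
                if (is.null(r$strata)) "<none>" else r$strata,
                if (is.null(r$psu)) "<none>" else r$psu))
  }
  cat("  confounders:", paste(r$confounders, collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read / write a survey dataset as CSV
#'
#' The column mapping (which columns play the outcome, exposure, weight,
#' stratum and PSU roles) travels in a small YAML sidecar so a dataset written
#' by one session can be reloaded without re-specifying roles.
#'
#' @param data a `svy_data` object.
#' @param path CSV file path; the mapping is written to `<path>.yaml`.
#' @return `write_survey_csv` returns `path` invisibly; `read_survey_csv`
#'   returns a `svy_data` object.
#' @export
write_survey_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  yaml::write_yaml(svy_roles(data), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_survey_csv
#' @param mapping optional named list overriding the sidecar mapping (fields as
#'   in [survey_dataset()]).
#' @export
read_survey_csv <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = TRUE)
  if (is.null(mapping)) {
    side <- paste0(path, ".yaml")
    if (!file.exists(side)) {
      stop("read_survey_csv: no mapping supplied and no sidecar ", side,
           call. = FALSE)
    }
    mapping <- yaml::read_yaml(side)
  }
  survey_dataset(df,
                 outcome = mapping$outcome, exposure = mapping$exposure,
                 weight = mapping$weight,
                 confounders = mapping$confounders %||% NULL,
                 strata = mapping$strata %||% NULL,
                 psu = mapping$psu %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
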