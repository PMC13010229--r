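# Adapter for NHANES-style public-release files: merges demographics, blood
# pressure, household smoking and income components on the respondent id and
# applies the eligibility and complete-case filters, producing a
# survey_dataset plus an ordered exclusion log. Variable names are
# configuration, not code: the public release renames variables across
# cycles, so the mapping below must be checked against the cycle's
# documentation before use on real downloads.

#' Variable mapping for NHANES-style files
#'
#' Defaults follow the widely used public-release names of the 2017-2020
#' pre-pandemic cycle (respondent id `SEQN`, MEC exam weight `WTMECPRP`,
#' design strata/PSU `SDMVSTRA`/`SDMVPSU`, oscillometric blood-pressure
#' readings `BPXOSY1..3`/`BPXODI1..3`, household smokers `SMD460`, income
#' ratio `INDFMPIR`). Every field is overridable; treat the defaults as a
#' starting point to verify, not as authority.
#'
#' @param id respondent id present in every file.
#' @param age age in years (demographics file).
#' @param sex,ethnicity demographic covariates.
#' @param mec_weight MEC exam weight variable.
#' @param strata,psu masked design variables.
#' @param sbp_readings,dbp_readings character vectors of systolic/diastolic
#'   reading columns; the outcome is the mean of the available readings.
#' @param smokers household-smoker count (or indicator) column; exposure is 1
#'   when the value is greater than zero.
#' @param pir poverty-to-income ratio column (income file).
#' @param poverty_cuts cutpoints turning `pir` into below/near/above poverty
#'   categories.
#' @param age_range inclusive eligible age range.
#' @param outcome `"sbp"` or `"dbp"`.
#' @return A list of class `nhanes_mapping`.
#' @export
nhanes_mapping <- function(id = "SEQN", age = "RIDAGEYR", sex = "RIAGENDR",
                           ethnicity = "RIDRETH3", mec_weight = "WTMECPRP",
                           strata = "SDMVSTRA", psu = "SDMVPSU",
                           sbp_readings = c("BPXOSY1", "BPXOSY2", "BPXOSY3"),
                           dbp_readings = c("BPXODI1", "BPXODI2", "BPXODI3"),
                           smokers = "SMD460", pir = "INDFMPIR",
                           poverty_cuts = c(1, 2), age_range = c(8, 11),
                           outcome = c("sbp", "dbp")) {
  outcome <- match.arg(outcome)
  structure(list(id = id, age = age, sex = sex, ethnicity = ethnicity,
                 mec_weight = mec_weight, strata = strata, psu = psu,
                 sbp_readings = sbp_readings, dbp_readings = dbp_readings,
                 smokers = smokers, pir = pir, poverty_cuts = poverty_cuts,
                 age_range = age_range, outcome = outcome),
            class = "nhanes_mapping")
}

# read a component file: SAS transport (.xpt) or CSV
.read_component <- function(path) {
  if (grepl("\\.xpt$", path, ignore.case = TRUE)) {
    foreign::read.xport(path)
  } else {
    utils::read.csv(path)
  }
}

.require_vars <- function(df, vars, file) {
  miss <- setdiff(vars, names(df))
  if (length(miss)) {
    stop("variable(s) ", paste(miss, collapse = ", "),
         " not found in ", file, "; fix the nhanes_mapping", call. = FALSE)
  }
}

#' Assemble an NHANES-style analysis dataset
#'
#' Merges the four component files on the respondent id, restricts to the
#' eligible age range with a nonmissing positive MEC exam weight, builds the
#' outcome as the mean of the available blood-pressure readings and the
#' exposure as an any-household-smoker indicator, applies the complete-case
#' filter (missing outcome first, then missing exposure, each counted
#' separately), and categorises the poverty-to-income ratio. Exclusions are
#' returned as an ordered log whose counts sum to the rows dropped.
#'
#' @param demographics_file,bp_file,smoking_file,income_file paths to the
#'   component files (`.xpt` SAS transport or `.csv`).
#' @param mapping an [nhanes_mapping()].
#' @return list with `data` (a [survey_dataset()] with confounders `age`,
#'   `sex`, `ethnicity`, `poverty`) and `exclusions` (named integer vector in
#'   filter order: `age`, `missing_weight`, `missing_outcome`,
#'   `missing_exposure`).
#' @examples
#' ext <- system.file("extdata", package = "svypate")
#' out <- build_analysis_dataset(
#'   file.path(ext, "synthetic_demo.csv"), file.path(ext, "synthetic_bpx.csv"),
#'   file.path(ext, "synthetic_smq.csv"), file.path(ext, "synthetic_inc.csv"))
#' out$exclusions
#' @export
build_analysis_dataset <- function(demographics_file, bp_file, smoking_file,
                                   income_file, mapping = nhanes_mapping()) {
  stopifnot(inherits(mapping, "nhanes_mapping"))
  m <- mapping
  demo <- .read_component(demographics_file)
  .require_vars(demo, c(m$id, m$age, m$sex, m$ethnicity, m$mec_weight,
                        m$strata, m$psu), demographics_file)
  bp <- .read_component(bp_file)
  readings <- if (m$outcome == "sbp") m$sbp_readings else m$dbp_readings
  .require_vars(bp, c(m$id, readings), bp_file)
  smoke <- .read_component(smoking_file)
  .require_vars(smoke, c(m$id, m$smokers), smoking_file)
  income <- .read_component(income_file)
  .require_vars(income, c(m$id, m$pir), income_file)

  df <- merge(demo, bp[, c(m$id, readings)], by = m$id, all.x = TRUE)
  df <- merge(df, smoke[, c(m$id, m$smokers)], by = m$id, all.x = TRUE)
  df <- merge(df, income[, c(m$id, m$pir)], by = m$id, all.x = TRUE)

  excl <- c(age = 0L, missing_weight = 0L, missing_outcome = 0L,
            missing_exposure = 0L)

  ok_age <- !is.na(df[[m$age]]) & df[[m$age]] >= m$age_range[1] &
    df[[m$age]] <= m$age_range[2]
  excl["age"] <- sum(!ok_age)
  df <- df[ok_age, , drop = FALSE]

  ok_w <- !is.na(df[[m$mec_weight]]) & df[[m$mec_weight]] > 0
  excl["missing_weight"] <- sum(!ok_w)
  df <- df[ok_w, , drop = FALSE]

  bp_mat <- as.matrix(df[, readings, drop = FALSE])
  outcome <- rowMeans(bp_mat, na.rm = TRUE)
  outcome[!is.finite(outcome)] <- NA_real_
  ok_y <- !is.na(outcome)
  excl["missing_outcome"] <- sum(!ok_y)
  df <- df[ok_y, , drop = FALSE]
  outcome <- outcome[ok_y]

  smokers <- df[[m$smokers]]
  exposure <- ifelse(is.na(smokers), NA_real_, as.numeric(smokers > 0))
  ok_a <- !is.na(exposure)
  excl["missing_exposure"] <- sum(!ok_a)
  df <- df[ok_a, , drop = FALSE]
  outcome <- outcome[ok_a]
  exposure <- exposure[ok_a]

  if (nrow(df) == 0) {
    stop("no rows remain after eligibility and complete-case filters",
         call. = FALSE)
  }

  poverty <- cut(df[[m$pir]],
                 breaks = c(-Inf, m$poverty_cuts, Inf),
                 labels = c("below", "near", "above"), right = FALSE)
  poverty <- factor(ifelse(is.na(poverty), "unknown", as.character(poverty)),
                    levels = c("below", "near", "above", "unknown"))

  out <- data.frame(
    id = df[[m$id]],
    Y = outcome,
    A = exposure,
    age = df[[m$age]],
    sex = factor(df[[m$sex]]),
    ethnicity = factor(df[[m$ethnicity]]),
    poverty = poverty,
    w = df[[m$mec_weight]],
    stratum = df[[m$strata]],
    # public-release PSU codes recycle across strata; make labels unique by
    # nesting them in the stratum
    psu = paste0(df[[m$strata]], "-", df[[m$psu]])
  )
  list(data = survey_dataset(out, outcome = "Y", exposure = "A", weight = "w",
                             confounders = c("age", "sex", "ethnicity",
                                             "poverty"),
                             strata = "stratum", psu = "psu"),
       exclusions = excl)
}
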