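COHORT_COLUMNS <- c("slide_id", "patient_id", "transformed",
                    "follow_up_months", "who_grade", "binary_grade",
                    "age", "sex", "site", "cohort_tag")

#' Read a cohort table
#'
#' The cohort CSV carries one row per slide with the clinical record used in
#' scoring and survival analyses: identifiers, transformation status,
#' follow-up in months, WHO (mild/moderate/severe) and binary
#' (low_risk/high_risk) grades, age, sex, intraoral site and a cohort tag
#' (internal/external). Rows with missing follow-up are retained (they remain
#' usable for model training) but flagged `eligible_survival = FALSE` and
#' excluded from outcome analyses. Missing grades are allowed and only
#' excluded from grade-specific analyses.
#'
#' @param path CSV path.
#' @return Validated cohort tibble with an added `eligible_survival` flag.
#' @export
read_cohort <- function(path) {
  assert_that(file.exists(path), sprintf("cohort file not found: %s", path),
              class = "odynr_io_error")
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_cohort(df)
}

#' Validate a cohort table
#'
#' Enforces the cohort invariants: required columns present, unique
#' `slide_id` (duplicates are a validation error naming the ids),
#' `transformed` binary, non-negative follow-up, and a single `cohort_tag`
#' per patient.
#'
#' @param df Data frame of slide records.
#' @return The cohort as a tibble with an `eligible_survival` flag.
#' @export
validate_cohort <- function(df) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  assert_that(length(missing_cols) == 0,
              sprintf("cohort table missing column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              class = "odynr_validation_error")
  dup <- unique(df$slide_id[duplicated(df$slide_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate slide_id(s): %s", paste(dup, collapse = ", ")),
          class = "odynr_validation_error")
  }
  assert_that(all(df$transformed %in% c(0, 1)),
              "`transformed` must be 0/1", class = "odynr_validation_error")
  fu <- df$follow_up_months
  assert_that(all(is.na(fu) | fu >= 0),
              "`follow_up_months` must be >= 0", class = "odynr_validation_error")
  ok_grade <- is.na(df$who_grade) | df$who_grade %in% c("mild", "moderate", "severe")
  assert_that(all(ok_grade), "invalid who_grade values",
              class = "odynr_validation_error")
  ok_bin <- is.na(df$binary_grade) | df$binary_grade %in% c("low_risk", "high_risk")
  assert_that(all(ok_bin), "invalid binary_grade values",
              class = "odynr_validation_error")
  tags_per_patient <- tapply(df$cohort_tag, df$patient_id,
                             function(x) length(unique(x)))
  assert_that(all(tags_per_patient == 1),
              "slides of one patient must share cohort_tag",
              class = "odynr_validation_error")
  out <- tibble::as_tibble(df)
  out$eligible_survival <- !is.na(out$follow_up_months)
  drop_log(sum(!out$eligible_survival),
           "slides without follow-up (ineligible for survival analyses)")
  out
}

#' Write a cohort table
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[, COHORT_COLUMNS], path)
  invisible(path)
}
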