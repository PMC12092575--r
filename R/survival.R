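#' Prepare survival records from a cohort
#'
#' Applies the analysis right-censoring horizon (default 96 months = eight
#' years) before any model fit: events after the horizon become censored at
#' the horizon, and follow-up is truncated. Slides flagged ineligible
#' (missing follow-up) are dropped with a logged count. Optional covariates
#' are joined from a score table.
#'
#' @param cohort Cohort tibble ([read_cohort()]).
#' @param scores Optional tibble with `slide_id` plus covariate columns
#'   (e.g. `odyn_score`, `risk_group`).
#' @param horizon_months Censoring horizon (default 96).
#' @return Tibble: `slide_id`, `patient_id`, `time_months`, `event`,
#'   remaining cohort covariates and any joined score columns.
#' @export
survival_records <- function(cohort, scores = NULL, horizon_months = 96) {
  co <- cohort[!is.na(cohort$follow_up_months), ]
  drop_log(nrow(cohort) - nrow(co), "slides without follow-up (dropped from survival)")
  out <- co |>
    dplyr::mutate(
      event = as.integer(.data$transformed == 1 &
                           .data$follow_up_months <= horizon_months),
      time_months = pmin(.data$follow_up_months, horizon_months)
    ) |>
    dplyr::select("slide_id", "patient_id", "time_months", "event",
                  "who_grade", "binary_grade", "age", "sex", "site",
                  "cohort_tag")
  if (!is.null(scores)) out <- dplyr::inner_join(out, scores, by = "slide_id")
  out
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit estimates per group (via the standard survival routines)
#' plus the log-rank chi-square with `groups - 1` degrees of freedom.
#'
#' @param records Survival records ([survival_records()]).
#' @param group Name of the grouping column (e.g. `"risk_group"`).
#' @return List: `curves` (tibble: group, time, n_risk, n_event, survival),
#'   `chisq`, `df`, `p_value`, `n`, `n_events`.
#' @export
km_logrank <- function(records, group) {
  g <- records[[group]]
  assert_that(!is.null(g), sprintf("no column `%s`", group))
  keep <- !is.na(g)
  records <- records[keep, ]; g <- g[keep]
  assert_that(length(unique(g)) >= 2, "need >= 2 groups",
              class = "odynr_validation_error")
  assert_that(sum(records$event) >= 1, "need >= 1 event",
              class = "odynr_validation_error")
  sf <- survival::survfit(
    survival::Surv(time_months, event) ~ grp,
    data = data.frame(time_months = records$time_months,
                      event = records$event, grp = g))
  strata_names <- sub("^grp=", "", rep(names(sf$strata), sf$strata))
  curves <- tibble::tibble(
    group = strata_names, time = sf$time, n_risk = sf$n.risk,
    n_event = sf$n.event, n_censor = sf$n.censor, survival = sf$surv)
  sd_ <- survival::survdiff(
    survival::Surv(time_months, event) ~ grp,
    data = data.frame(time_months = records$time_months,
                      event = records$event, grp = g))
  df <- length(unique(g)) - 1
  p <- stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE)
  list(curves = curves, chisq = unname(sd_$chisq), df = df, p_value = p,
       n = nrow(records), n_events = sum(records$event))
}

#' Harrell's concordance index
#'
#' Rank correlation between a risk score and right-censored survival:
#' over admissible pairs (the earlier time is an event), the fraction where
#' the shorter-lived subject has the higher risk score; score ties count
#' one half.
#'
#' @param scores Risk scores (higher = riskier).
#' @param times Follow-up times.
#' @param events Event indicators (1 = event).
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(scores, times, events) {
  n <- length(scores)
  stopifnot(length(times) == n, length(events) == n)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    comparable <- which(times > times[i] | (times == times[i] & events == 0))
    if (length(comparable) == 0) next
    den <- den + length(comparable)
    num <- num + sum(scores[i] > scores[comparable]) +
      0.5 * sum(scores[i] == scores[comparable])
  }
  assert_that(den > 0, "no comparable pairs: C-index undefined",
              class = "odynr_validation_error")
  num / den
}

#' Multivariate Cox proportional hazards model
#'
#' Partial-likelihood fit with Efron tie handling, delegating to the
#' established survival machinery; the contract is the returned per-covariate
#' hazard ratios with Wald 95% confidence intervals and p-values. The
#' standard incorporation is the risk score (or a grade) plus sex and age,
#' with lesion site added for internal cohorts.
#'
#' @param records Survival records ([survival_records()]).
#' @param covariates Character vector of covariate column names.
#' @return Tibble: `term`, `log_hr`, `hr`, `hr_lo`, `hr_hi`, `p_value`, `n`,
#'   `n_events`.
#' @export
cox_multivariate <- function(records, covariates) {
  for (cv in covariates) {
    assert_that(!is.null(records[[cv]]), sprintf("no column `%s`", cv))
  }
  dat <- records[stats::complete.cases(records[, c("time_months", "event",
                                                   covariates)]), ]
  assert_that(sum(dat$event) >= length(covariates) + 1,
              "too few events for the requested covariates",
              class = "odynr_validation_error")
  for (cv in covariates) {
    assert_that(length(unique(dat[[cv]])) > 1,
                sprintf("constant covariate `%s`", cv),
                class = "odynr_validation_error")
  }
  f <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                               paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = dat, ties = "efron")
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    abort("Cox model did not converge", class = "odynr_convergence_error")
  }
  s <- summary(fit)
  ci <- s$conf.int
  tibble::tibble(
    term = rownames(s$coefficients),
    log_hr = unname(s$coefficients[, "coef"]),
    hr = unname(s$coefficients[, "exp(coef)"]),
    hr_lo = unname(ci[, "lower .95"]),
    hr_hi = unname(ci[, "upper .95"]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"]),
    n = nrow(dat), n_events = sum(dat$event)
  )
}

#' WHO-grade stratifications used in survival comparisons
#'
#' G1 dichotomises mild vs moderate/severe; G2 dichotomises mild/moderate vs
#' severe. Missing grades stay missing (excluded from grade analyses only).
#'
#' @param who_grade Character vector of `mild`/`moderate`/`severe`.
#' @return Tibble with `who_g1` and `who_g2` factors (`low`/`high`).
#' @export
who_stratifications <- function(who_grade) {
  tibble::tibble(
    who_g1 = ifelse(is.na(who_grade), NA_character_,
                    ifelse(who_grade == "mild", "low", "high")),
    who_g2 = ifelse(is.na(who_grade), NA_character_,
                    ifelse(who_grade == "severe", "high", "low"))
  )
}
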