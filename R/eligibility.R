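#' Average daily alcohol consumption
#'
#' Combines the two standard questionnaire items — days drank in the past 12
#' months and usual drinks per drinking day — into a daily average:
#' `days_per_year * drinks_per_day / 365`.
#'
#' @param days_per_year Days drank in the past year, 0–365.
#' @param drinks_per_day Usual drinks on a drinking day (non-negative).
#' @return Average drinks/day (vectorized).
#' @examples
#' daily_alcohol_average(73, 5) # 1 drink/day
#' @export
daily_alcohol_average <- function(days_per_year, drinks_per_day) {
  if (any(days_per_year < 0 | days_per_year > 365, na.rm = TRUE)) {
    stop("days_per_year must lie in [0, 365]")
  }
  if (any(drinks_per_day < 0, na.rm = TRUE)) stop("drinks_per_day must be >= 0")
  days_per_year * drinks_per_day / 365
}

#' Excessive alcohol use
#'
#' More than two drinks/day for men or more than one drink/day for women.
#' The bounds are strict: exactly 2 (men) or 1 (women) drinks/day is not
#' excessive.
#'
#' @param avg Average drinks/day, e.g. from [daily_alcohol_average()].
#' @param sex `"male"` or `"female"` (vectorized).
#' @return Logical vector.
#' @export
is_excessive_alcohol <- function(avg, sex) {
  if (any(avg < 0, na.rm = TRUE)) stop("avg must be >= 0")
  ifelse(sex == "male", avg > 2, avg > 1)
}

#' Chronic viral hepatitis flags
#'
#' Chronic hepatitis B requires positivity on both the surface antigen
#' (HBsAg) and core antibody (anti-HBc) tests; chronic hepatitis C requires
#' both a positive antibody and a positive RNA test. A missing serology flag
#' is treated as negative — exclusion requires positive evidence on both
#' tests — with a warning when every flag is missing for some subject.
#'
#' @param cohort Cohort data.frame (see [cohort_schema()]).
#' @return Logical vector, one element per subject.
#' @export
chronic_hep_b <- function(cohort) {
  both_missing <- is.na(cohort$hbsag_positive) & is.na(cohort$anti_hbc_positive)
  if (any(both_missing)) {
    warning(sum(both_missing),
            " subject(s) with all hepatitis B serology missing; treated as negative")
  }
  isTRUE_vec(cohort$hbsag_positive) & isTRUE_vec(cohort$anti_hbc_positive)
}

#' @rdname chronic_hep_b
#' @export
chronic_hep_c <- function(cohort) {
  both_missing <- is.na(cohort$hcv_ab_positive) & is.na(cohort$hcv_rna_positive)
  if (any(both_missing)) {
    warning(sum(both_missing),
            " subject(s) with all hepatitis C serology missing; treated as negative")
  }
  isTRUE_vec(cohort$hcv_ab_positive) & isTRUE_vec(cohort$hcv_rna_positive)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Ordered exclusion reasons
#'
#' The fixed precedence order used by [apply_exclusions()]: each subject is
#' excluded at most once, under the first matching reason.
#'
#' @return Character vector of reason codes.
#' @export
exclusion_reasons <- function() {
  c("age_out_of_range", "ultrasound_missing_or_ungradable", "chronic_hep_b",
    "chronic_hep_c", "transferrin_gt_50", "excessive_alcohol",
    "steatogenic_medication", "listwise_missing")
}

#' Fields required complete for the default analysis
#'
#' The score inputs plus the regression covariates used in the default
#' pipeline; subjects missing any of these are dropped by listwise deletion.
#'
#' @return Character vector of column names.
#' @export
default_required_fields <- function() {
  c("age", "sex", "race_ethnicity", "waist_cm", "hip_cm", "systolic_bp",
    "diastolic_bp", "htn_diagnosis", "htn_medication", "dm_diagnosis",
    "fasting_glucose", "fasting_insulin", "alt", "ast", "hdl", "triglyceride",
    "alcohol_days_per_year", "alcohol_drinks_per_day")
}

#' Apply eligibility and exclusion criteria
#'
#' Retains subjects aged 20–74 (inclusive) with a gradable ultrasound, no
#' chronic hepatitis B or C, transferrin saturation at most 50 percent,
#' non-excessive alcohol use, no steatogenic prescription medication, and no
#' missing value among `required_fields` (listwise deletion). Each excluded
#' subject is tallied once, under the first matching reason in the order of
#' [exclusion_reasons()]; retained subjects keep their input order.
#'
#' @param cohort Cohort data.frame.
#' @param required_fields Columns subjected to listwise deletion.
#' @param age_range Inclusive eligible age bounds.
#' @return A list of class `"exclusion_result"` with `cohort` (the retained
#'   analysis cohort), `tally` (named integer counts per reason), `n_input`,
#'   and `n_retained`. The partition invariant
#'   `n_input == n_retained + sum(tally)` always holds.
#' @export
apply_exclusions <- function(cohort, required_fields = default_required_fields(),
                             age_range = c(20L, 74L)) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("cohort must be a non-empty data.frame")
  }
  bad <- setdiff(required_fields, names(cohort))
  if (length(bad)) stop("required_fields not in cohort: ", paste(bad, collapse = ", "))

  avg <- daily_alcohol_average(cohort$alcohol_days_per_year,
                               cohort$alcohol_drinks_per_day)
  checks <- list(
    age_out_of_range = is.na(cohort$age) | cohort$age < age_range[1] |
      cohort$age > age_range[2],
    ultrasound_missing_or_ungradable = is.na(cohort$ultrasound_grade) |
      cohort$ultrasound_grade %in% c("ungradable", "missing"),
    chronic_hep_b = chronic_hep_b(cohort),
    chronic_hep_c = chronic_hep_c(cohort),
    transferrin_gt_50 = isTRUE_vec(cohort$transferrin_saturation > 50),
    excessive_alcohol = isTRUE_vec(is_excessive_alcohol(avg, cohort$sex)),
    steatogenic_medication = isTRUE_vec(cohort$steatogenic_medication),
    listwise_missing = Reduce(`|`, lapply(required_fields,
                                          function(f) is.na(cohort[[f]])))
  )
  reason <- rep(NA_character_, nrow(cohort))
  for (r in exclusion_reasons()) {
    reason[is.na(reason) & checks[[r]]] <- r
  }
  tally <- vapply(exclusion_reasons(),
                  function(r) sum(reason == r, na.rm = TRUE), integer(1))
  keep <- is.na(reason)
  out <- list(cohort = cohort[keep, , drop = FALSE], tally = tally,
              n_input = nrow(cohort), n_retained = sum(keep))
  rownames(out$cohort) <- NULL
  class(out) <- "exclusion_result"
  out
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat(format_flow_report(x), sep = "\n")
  invisible(x)
}

#' Plain-text participant-flow report
#'
#' Renders the exclusion tally as the kind of flow summary that accompanies
#' a cohort flow diagram.
#'
#' @param x An `"exclusion_result"` from [apply_exclusions()].
#' @return Character vector of report lines.
#' @export
format_flow_report <- function(x) {
  lines <- c(sprintf("Eligible input subjects: %d", x$n_input))
  running <- x$n_input
  for (r in exclusion_reasons()) {
    if (x$tally[[r]] > 0) {
      running <- running - x$tally[[r]]
      lines <- c(lines, sprintf("  excluded, %s: %d (remaining %d)",
                                gsub("_", " ", r), x$tally[[r]], running))
    }
  }
  c(lines, sprintf("Analysis cohort: %d", x$n_retained))
}

#' Exclusion tally as JSON
#'
#' @param x An `"exclusion_result"`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
exclusion_tally_json <- function(x, path = NULL) {
  obj <- list(n_input = x$n_input, n_retained = x$n_retained,
              exclusions = as.list(x$tally))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
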