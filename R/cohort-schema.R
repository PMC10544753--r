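#' Column schema of a subject-level cohort table
#'
#' A cohort is an ordinary `data.frame` with one row per survey participant
#' and a fixed, documented set of columns: demographics, anthropometrics,
#' laboratory values, viral-hepatitis serology, the ultrasound steatosis
#' grade, and the complex-survey design variables (stratum, PSU, sampling
#' weight). `cohort_schema()` returns the machine-readable description used
#' by [read_cohort()], [write_cohort()] and [validate_cohort()].
#'
#' Column types are `"integer"`, `"real"`, `"logical"`, `"character"` and
#' `"categorical"`; categorical columns carry their legal level sets.
#' Units follow NHANES laboratory conventions: glucose in mg/dL, insulin in
#' uU/mL (= mU/L), C-peptide in nmol/L, CRP in mg/dL, transferrin saturation
#' in percent. See [insulin_pmol_to_uU()] for unit conversion helpers.
#'
#' @return A data.frame with columns `column`, `type`, `required`
#'   (needed by the scoring/eligibility stages), and `levels`
#'   (comma-separated legal values for categorical columns, else `NA`).
#' @examples
#' head(cohort_schema())
#' @export
cohort_schema <- function() {
  s <- function(column, type, required, levels = NA_character_) {
    data.frame(column = column, type = type, required = required,
               levels = levels, stringsAsFactors = FALSE)
  }
  rbind(
    s("subject_id", "character", TRUE),
    s("age", "integer", TRUE),
    s("sex", "categorical", TRUE, "male,female"),
    s("race_ethnicity", "categorical", TRUE, "white,black,mexican_american,other"),
    s("education", "categorical", FALSE, "lt_hs,hs,gt_hs"),
    s("poverty_ratio", "real", FALSE),
    s("urbanization", "categorical", FALSE, "urban,rural"),
    s("birthplace", "categorical", FALSE, "us,mexico,other"),
    s("years_in_us", "categorical", FALSE, "entire_life,lt5,5to10,gt10"),
    s("smoking", "categorical", FALSE, "never,former,current"),
    s("alcohol_days_per_year", "integer", TRUE),
    s("alcohol_drinks_per_day", "real", TRUE),
    s("ever_12_drinks_lifetime", "logical", FALSE),
    s("twelve_drinks_past_year", "logical", FALSE),
    s("activity_level", "categorical", FALSE,
      "inactive,below_guidelines,meets_guidelines"),
    s("waist_cm", "real", TRUE),
    s("hip_cm", "real", TRUE),
    s("systolic_bp", "real", TRUE),
    s("diastolic_bp", "real", TRUE),
    s("htn_diagnosis", "logical", TRUE),
    s("htn_medication", "logical", TRUE),
    s("dm_diagnosis", "logical", TRUE),
    s("fasting_glucose", "real", TRUE),
    s("two_hr_glucose", "real", FALSE),
    s("fasting_insulin", "real", TRUE),
    s("c_peptide", "real", FALSE),
    s("alt", "real", TRUE),
    s("ast", "real", TRUE),
    s("total_cholesterol", "real", FALSE),
    s("hdl", "real", TRUE),
    s("triglyceride", "real", TRUE),
    s("crp", "real", FALSE),
    s("hba1c", "real", FALSE),
    s("transferrin_saturation", "real", TRUE),
    s("hbsag_positive", "logical", TRUE),
    s("anti_hbc_positive", "logical", TRUE),
    s("hcv_ab_positive", "logical", TRUE),
    s("hcv_rna_positive", "logical", TRUE),
    s("steatogenic_medication", "logical", TRUE),
    s("hei_score", "real", FALSE),
    s("ultrasound_grade", "categorical", TRUE,
      "none,mild,moderate,severe,ungradable,missing"),
    s("stratum", "character", TRUE),
    s("psu", "character", TRUE),
    s("weight", "real", TRUE)
  )
}

schema_levels <- function(schema_row) {
  strsplit(schema_row$levels, ",", fixed = TRUE)[[1]]
}

#' Validate a cohort table against the schema
#'
#' Checks column presence, types, categorical levels and the record
#' invariants: non-negative ages, labs and anthropometrics, strictly
#' positive sampling weights, and `hip_cm > 0` wherever `waist_cm` is
#' present (so the waist-hip ratio is well defined).
#'
#' @param cohort data.frame as described in [cohort_schema()].
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("cohort must be a non-empty data.frame")
  }
  sch <- cohort_schema()
  missing_cols <- setdiff(sch$column, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(sch))) {
    col <- sch$column[i]
    x <- cohort[[col]]
    type <- sch$type[i]
    ok <- switch(type,
      integer = is.numeric(x),
      real = is.numeric(x),
      logical = is.logical(x),
      character = is.character(x) || is.factor(x),
      categorical = is.character(x) || is.factor(x))
    if (!ok) stop(sprintf("column '%s' has wrong type (expected %s)", col, type))
    if (type == "categorical") {
      lv <- schema_levels(sch[i, ])
      bad <- setdiff(unique(as.character(x[!is.na(x)])), lv)
      if (length(bad)) {
        stop(sprintf("column '%s' has illegal value(s): %s", col,
                     paste(bad, collapse = ", ")))
      }
    }
  }
  nonneg <- c("age", "poverty_ratio", "alcohol_days_per_year",
              "alcohol_drinks_per_day", "waist_cm", "hip_cm", "systolic_bp",
              "diastolic_bp", "fasting_glucose", "two_hr_glucose",
              "fasting_insulin", "c_peptide", "alt", "ast",
              "total_cholesterol", "hdl", "triglyceride", "crp", "hba1c",
              "transferrin_saturation", "hei_score")
  for (col in nonneg) {
    x <- cohort[[col]]
    if (any(!is.na(x) & x < 0)) stop(sprintf("column '%s' has negative values", col))
  }
  if (any(is.na(cohort$weight) | cohort$weight <= 0)) {
    stop("column 'weight' must be present and > 0 for every subject")
  }
  if (any(cohort$alcohol_days_per_year > 365, na.rm = TRUE)) {
    stop("alcohol_days_per_year exceeds 365")
  }
  bad_hip <- !is.na(cohort$waist_cm) & (is.na(cohort$hip_cm) | cohort$hip_cm <= 0)
  if (any(bad_hip)) stop("hip_cm must be > 0 whenever waist_cm is present")
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads a subject-level CSV (RFC 4180, UTF-8, header row) into a cohort
#' data.frame. Files whose columns are named differently from the canonical
#' schema — e.g. an extract from a survey data release — are adapted through
#' `dialect`, a named character vector mapping canonical names to the file's
#' column names, without any code change. Empty cells become `NA`; a missing
#' value is never silently coerced to zero.
#'
#' @param path CSV file path.
#' @param dialect Optional named character vector, `canonical = "file_column"`.
#'   Unmapped canonical names are looked up verbatim.
#' @return A validated cohort data.frame, rows in file order.
#' @seealso [write_cohort()], [cohort_schema()]
#' @export
read_cohort <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  sch <- cohort_schema()
  out <- vector("list", nrow(sch))
  names(out) <- sch$column
  for (i in seq_len(nrow(sch))) {
    canon <- sch$column[i]
    src <- if (!is.null(dialect) && canon %in% names(dialect)) dialect[[canon]] else canon
    if (!src %in% names(raw)) {
      stop(sprintf("required column '%s' (file column '%s') not found in %s",
                   canon, src, path))
    }
    x <- raw[[src]]
    type <- sch$type[i]
    out[[canon]] <- switch(type,
      integer = parse_num(x, canon, as_integer = TRUE),
      real = parse_num(x, canon),
      logical = parse_bool(x, canon),
      character = as.character(x),
      categorical = as.character(x))
  }
  cohort <- as.data.frame(out, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

parse_num <- function(x, col, as_integer = FALSE) {
  if (is.logical(x)) x <- as.numeric(x)  # all-NA columns read as logical
  if (is.character(x)) {
    bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
    if (any(bad)) {
      stop(sprintf("non-numeric value in column '%s' at row %d: '%s'",
                   col, which(bad)[1], x[which(bad)[1]]))
    }
    x <- as.numeric(x)
  }
  if (as_integer) x <- as.integer(round(x))
  x
}

parse_bool <- function(x, col) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(x) & x != "na" & is.na(out)
  if (any(bad)) {
    stop(sprintf("non-boolean value in column '%s' at row %d: '%s'",
                 col, which(bad)[1], x[which(bad)[1]]))
  }
  out
}

#' Write a cohort CSV
#'
#' Writes the cohort with the stable canonical header of [cohort_schema()].
#' Missing values are written as empty cells and round-trip through
#' [read_cohort()] unchanged.
#'
#' @param cohort Validated cohort data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, cohort_schema()$column], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Laboratory unit conversions
#'
#' The score formulas expect NHANES conventional units: fasting insulin in
#' uU/mL (numerically equal to mU/L) and glucose in mg/dL. Laboratories
#' reporting SI units can convert with these helpers: insulin pmol/L is
#' divided by 6.0; glucose mmol/L is multiplied by 18.0.
#'
#' @param x Numeric vector of lab values.
#' @return Converted numeric vector.
#' @examples
#' insulin_pmol_to_uU(60) # 10 uU/mL
#' glucose_mmol_to_mgdl(5)  # 90 mg/dL
#' @export
insulin_pmol_to_uU <- function(x) x / 6.0

#' @rdname insulin_pmol_to_uU
#' @export
glucose_mmol_to_mgdl <- function(x) x * 18.0
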