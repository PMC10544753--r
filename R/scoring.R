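#' Score coefficients and category thresholds
#'
#' Single source of truth for every cutoff and coefficient used by the
#' scoring stage. Defaults are the published values of the three scoring
#' systems and the standard clinical category boundaries; any entry can be
#' overridden, e.g. to probe cutoff sensitivity.
#'
#' Boundary conventions where printed category edges overlap are fixed here
#' once: total cholesterol normal <= 200, elevated (200, 240), high >= 240;
#' CRP normal < 0.3, mild \[0.3, 1\], significant > 1; C-peptide low < 0.26,
#' normal \[0.26, 1.03\], high > 1.03; HEI poor < 50, needs improvement
#' \[50, 80\], good > 80.
#'
#' @param ... Named overrides of the default entries.
#' @return Named list of thresholds and coefficients.
#' @examples
#' nash_thresholds(hair_homa_cut = 4)$hair_homa_cut
#' @export
nash_thresholds <- function(...) {
  defaults <- list(
    # HAIR: one point each, positive at >= hair_positive_points
    hair_homa_cut = 5, hair_alt_cut = 40,
    hair_sbp_cut = 140, hair_dbp_cut = 90, hair_positive_points = 2L,
    # Gholam: a * ln(AST) + b * [type-2 diabetes]; diabetes by prior
    # diagnosis or fasting glucose strictly > gholam_glucose_cut
    gholam_ast_coef = 2.627, gholam_dm_coef = 2.13, gholam_cutoff = 8.22,
    gholam_glucose_cut = 126,
    # NASH liver fat score; diabetes (coded 0/2) by diagnosis, fasting
    # glucose >= lfs_glucose_cut, or 2-hour glucose >= lfs_2h_glucose_cut
    lfs_ms_coef = 1.18, lfs_dm_coef = 0.45, lfs_insulin_coef = 0.15,
    lfs_ast_coef = 0.04, lfs_ratio_coef = -0.94, lfs_intercept = -2.89,
    lfs_cutoff = 2.122, lfs_cutoff_inclusive = TRUE,
    lfs_glucose_cut = 126, lfs_2h_glucose_cut = 200,
    # metabolic syndrome (>= 3 of 5); bp rule "and" = sbp>=130 AND dbp>=85
    ms_waist_male = 94, ms_waist_female = 80, ms_triglyceride = 150,
    ms_hdl_male = 40, ms_hdl_female = 50, ms_sbp = 130, ms_dbp = 85,
    ms_glucose = 100, ms_bp_rule = "and",
    # covariate categories
    whr_male = 0.90, whr_female = 0.85,
    c_peptide_low = 0.26, c_peptide_high = 1.03,
    chol_elevated = 200, chol_high = 240,
    crp_mild = 0.3, crp_significant = 1,
    hei_poor = 50, hei_good = 80,
    age_breaks = c(20, 35, 50, 65, 75)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  defaults[names(dots)] <- dots
  defaults
}

#' HOMA-IR insulin-resistance index
#'
#' Homeostatic model assessment of insulin resistance by the Matthews
#' formula with conventional units:
#' `fasting glucose (mg/dL) x fasting insulin (uU/mL) / 405`.
#'
#' @param fasting_glucose mg/dL, > 0.
#' @param fasting_insulin uU/mL, > 0.
#' @return HOMA-IR (vectorized).
#' @examples
#' compute_homa_ir(90, 4.5) # 1.0
#' @export
compute_homa_ir <- function(fasting_glucose, fasting_insulin) {
  if (any(fasting_glucose <= 0 | fasting_insulin <= 0, na.rm = TRUE)) {
    stop("fasting glucose and insulin must be > 0")
  }
  fasting_glucose * fasting_insulin / 405
}

#' HAIR score
#'
#' One point each for HOMA-IR > 5, ALT > 40 U/L, and hypertension (blood
#' pressure >= 140/90 mmHg, a prior hypertension diagnosis, or hypertension
#' medication). Positive — probable NASH among NAFLD subjects — at >= 2
#' points.
#'
#' @param homa_ir HOMA-IR index.
#' @param alt ALT, U/L.
#' @param sbp,dbp Blood pressure, mmHg.
#' @param htn_diagnosis,htn_medication Logical.
#' @param thresholds See [nash_thresholds()].
#' @return List with `points` (integer 0–3) and `positive` (logical),
#'   vectorized over subjects.
#' @export
hair_score <- function(homa_ir, alt, sbp, dbp, htn_diagnosis, htn_medication,
                       thresholds = nash_thresholds()) {
  th <- thresholds
  hypertensive <- (sbp >= th$hair_sbp_cut | dbp >= th$hair_dbp_cut) |
    isTRUE_vec(htn_diagnosis) | isTRUE_vec(htn_medication)
  points <- (homa_ir > th$hair_homa_cut) + (alt > th$hair_alt_cut) + hypertensive
  list(points = as.integer(points), positive = points >= th$hair_positive_points)
}

#' Gholam score
#'
#' `2.627 * ln(AST) + 2.13` for subjects with type-2 diabetes (prior
#' diagnosis or fasting glucose > 126 mg/dL). Positive at a value >= 8.22.
#'
#' @param ast AST, U/L, > 0.
#' @param diabetes Logical; use [derive_features()]' `diabetes_gholam`.
#' @param thresholds See [nash_thresholds()].
#' @return List with `value` and `positive`, vectorized.
#' @export
gholam_score <- function(ast, diabetes, thresholds = nash_thresholds()) {
  if (any(ast <= 0, na.rm = TRUE)) stop("ast must be > 0")
  th <- thresholds
  value <- th$gholam_ast_coef * log(ast) + th$gholam_dm_coef * isTRUE_vec(diabetes)
  list(value = value, positive = value >= th$gholam_cutoff)
}

#' Metabolic syndrome (harmonized 5-criterion definition)
#'
#' At least 3 of: waist circumference > 94 cm (men) / > 80 cm (women);
#' fasting triglyceride >= 150 mg/dL; HDL < 40 (men) / < 50 (women) mg/dL;
#' blood pressure >= 130/85 mmHg or treated hypertension; fasting glucose
#' >= 100 mg/dL or treated hyperglycemia. The blood-pressure criterion
#' requires both limbs (systolic and diastolic) by default; set
#' `ms_bp_rule = "or"` in [nash_thresholds()] for the either-limb reading.
#'
#' @param waist_cm,sex,triglyceride,hdl,sbp,dbp,fasting_glucose Subject values.
#' @param htn_treated,glycemia_treated Logical treatment flags.
#' @param thresholds See [nash_thresholds()].
#' @return Logical vector.
#' @export
metabolic_syndrome <- function(waist_cm, sex, triglyceride, hdl, sbp, dbp,
                               htn_treated, fasting_glucose, glycemia_treated,
                               thresholds = nash_thresholds()) {
  th <- thresholds
  male <- sex == "male"
  c_waist <- waist_cm > ifelse(male, th$ms_waist_male, th$ms_waist_female)
  c_tg <- triglyceride >= th$ms_triglyceride
  c_hdl <- hdl < ifelse(male, th$ms_hdl_male, th$ms_hdl_female)
  bp_high <- if (identical(th$ms_bp_rule, "or")) {
    sbp >= th$ms_sbp | dbp >= th$ms_dbp
  } else {
    sbp >= th$ms_sbp & dbp >= th$ms_dbp
  }
  c_bp <- bp_high | isTRUE_vec(htn_treated)
  c_glu <- fasting_glucose >= th$ms_glucose | isTRUE_vec(glycemia_treated)
  (c_waist + c_tg + c_hdl + c_bp + c_glu) >= 3
}

#' NASH liver fat score
#'
#' `1.18*MS + 0.45*DM + 0.15*insulin + 0.04*AST - 0.94*(AST/ALT) - 2.89`,
#' with metabolic syndrome coded 0/1 and type-2 diabetes coded 0/2
#' (diagnosis, fasting glucose >= 126 mg/dL, or 2-hour glucose >= 200
#' mg/dL). Insulin is fasting insulin in uU/mL (mU/L). Positive at a value
#' >= 2.122 (strict `>` available via `lfs_cutoff_inclusive = FALSE`).
#'
#' @param ms Logical, metabolic syndrome.
#' @param diabetes Logical; use [derive_features()]' `diabetes_lfs`.
#' @param fasting_insulin uU/mL, >= 0.
#' @param ast AST U/L, >= 0.
#' @param alt ALT U/L, > 0 (the AST/ALT ratio must be defined).
#' @param thresholds See [nash_thresholds()].
#' @return List with `value` and `positive`, vectorized.
#' @export
nash_lfs <- function(ms, diabetes, fasting_insulin, ast, alt,
                     thresholds = nash_thresholds()) {
  if (any(alt <= 0, na.rm = TRUE)) stop("alt must be > 0 (AST/ALT undefined)")
  if (any(ast < 0 | fasting_insulin < 0, na.rm = TRUE)) {
    stop("ast and fasting_insulin must be >= 0")
  }
  th <- thresholds
  value <- th$lfs_ms_coef * isTRUE_vec(ms) +
    th$lfs_dm_coef * 2 * isTRUE_vec(diabetes) +
    th$lfs_insulin_coef * fasting_insulin +
    th$lfs_ast_coef * ast +
    th$lfs_ratio_coef * (ast / alt) +
    th$lfs_intercept
  positive <- if (isTRUE(th$lfs_cutoff_inclusive)) value >= th$lfs_cutoff
              else value > th$lfs_cutoff
  list(value = value, positive = positive)
}

#' Per-subject derived clinical features
#'
#' Computes the quantities the scores and the statistical stage need:
#' HOMA-IR, average daily alcohol, waist-hip ratio, metabolic syndrome,
#' the two score-specific diabetes definitions (the Gholam score uses prior
#' diagnosis or fasting glucose strictly > 126 mg/dL; the liver fat score
#' uses diagnosis, fasting glucose >= 126, or 2-hour glucose >= 200),
#' hypertension, and the categorized covariates of
#' [categorize_covariates()].
#'
#' @param cohort Cohort data.frame.
#' @param thresholds See [nash_thresholds()].
#' @return data.frame aligned with `cohort` rows.
#' @export
derive_features <- function(cohort, thresholds = nash_thresholds()) {
  th <- thresholds
  homa <- compute_homa_ir(cohort$fasting_glucose, cohort$fasting_insulin)
  treated_htn <- isTRUE_vec(cohort$htn_medication)
  treated_gly <- isTRUE_vec(cohort$dm_diagnosis)
  ms <- metabolic_syndrome(cohort$waist_cm, cohort$sex, cohort$triglyceride,
                           cohort$hdl, cohort$systolic_bp, cohort$diastolic_bp,
                           treated_htn, cohort$fasting_glucose, treated_gly,
                           thresholds = th)
  two_hr <- cohort$two_hr_glucose
  dm_lfs <- isTRUE_vec(cohort$dm_diagnosis) |
    cohort$fasting_glucose >= th$lfs_glucose_cut |
    (!is.na(two_hr) & two_hr >= th$lfs_2h_glucose_cut)
  dm_gholam <- isTRUE_vec(cohort$dm_diagnosis) |
    cohort$fasting_glucose > th$gholam_glucose_cut
  hypertension <- cohort$systolic_bp >= th$hair_sbp_cut |
    cohort$diastolic_bp >= th$hair_dbp_cut |
    isTRUE_vec(cohort$htn_diagnosis) | isTRUE_vec(cohort$htn_medication)
  base <- data.frame(
    homa_ir = homa,
    daily_alcohol = daily_alcohol_average(cohort$alcohol_days_per_year,
                                          cohort$alcohol_drinks_per_day),
    whr = cohort$waist_cm / cohort$hip_cm,
    metabolic_syndrome = ms,
    diabetes_lfs = dm_lfs,
    diabetes_gholam = dm_gholam,
    hypertension = hypertension,
    stringsAsFactors = FALSE)
  cbind(base, categorize_covariates(cohort, thresholds = th))
}

#' Categorize regression covariates
#'
#' Applies the standard clinical category boundaries (see
#' [nash_thresholds()] for the boundary conventions): 4-level age group
#' (20–34, 35–49, 50–64, 65–74), waist-hip-ratio risk (at-risk at >= 0.90
#' for men, >= 0.85 for women), C-peptide, total cholesterol, CRP and
#' healthy-eating-index categories, federal-poverty-level category, and
#' alcohol status from the two lifetime/past-year screening questions
#' (never / former / current).
#'
#' @param cohort Cohort data.frame.
#' @param thresholds See [nash_thresholds()].
#' @return data.frame of factors aligned with `cohort` rows; missing inputs
#'   yield missing categories.
#' @export
categorize_covariates <- function(cohort, thresholds = nash_thresholds()) {
  th <- thresholds
  cut3 <- function(x, lo, hi, labels) {
    # boundary convention: lower edge inclusive in the middle band
    f <- rep(NA_character_, length(x))
    f[!is.na(x) & x < lo] <- labels[1]
    f[!is.na(x) & x >= lo & x <= hi] <- labels[2]
    f[!is.na(x) & x > hi] <- labels[3]
    factor(f, levels = labels)
  }
  age_group <- cut(cohort$age, breaks = th$age_breaks, right = FALSE,
                   labels = c("20_34", "35_49", "50_64", "65_plus"))
  whr <- cohort$waist_cm / cohort$hip_cm
  whr_cut <- ifelse(cohort$sex == "male", th$whr_male, th$whr_female)
  whr_risk <- factor(ifelse(is.na(whr), NA,
                            ifelse(whr >= whr_cut, "at_risk", "healthy")),
                     levels = c("healthy", "at_risk"))
  chol <- rep(NA_character_, nrow(cohort))
  tc <- cohort$total_cholesterol
  chol[!is.na(tc) & tc <= th$chol_elevated] <- "normal"   # <= 200 is normal
  chol[!is.na(tc) & tc > th$chol_elevated & tc < th$chol_high] <- "elevated"
  chol[!is.na(tc) & tc >= th$chol_high] <- "high"
  alcohol_status <- factor(
    ifelse(is.na(cohort$ever_12_drinks_lifetime), NA,
      ifelse(!cohort$ever_12_drinks_lifetime, "never",
        ifelse(isTRUE_vec(cohort$twelve_drinks_past_year), "current", "former"))),
    levels = c("never", "former", "current"))
  pr <- cohort$poverty_ratio
  poverty_cat <- factor(
    ifelse(is.na(pr), NA,
      ifelse(pr < 1, "lt1", ifelse(pr <= 2, "1to2", "gt2"))),
    levels = c("gt2", "1to2", "lt1"))
  data.frame(
    age_group = age_group,
    whr_risk = whr_risk,
    c_peptide_cat = cut3(cohort$c_peptide, th$c_peptide_low, th$c_peptide_high,
                         c("low", "normal", "high")),
    chol_cat = factor(chol, levels = c("normal", "elevated", "high")),
    crp_cat = cut3(cohort$crp, th$crp_mild, th$crp_significant,
                   c("normal", "mild", "significant")),
    hei_cat = cut3(cohort$hei_score, th$hei_poor, th$hei_good,
                   c("poor", "needs_improvement", "good")),
    alcohol_status = alcohol_status,
    poverty_cat = poverty_cat,
    stringsAsFactors = FALSE)
}

#' Classify a cohort into normal / simple NAFLD / NASH per method
#'
#' NAFLD is moderate-to-severe steatosis on ultrasound; each method then
#' flags NASH only within the NAFLD set: a NAFLD subject is NASH by a
#' method when that method's score is positive, simple NAFLD otherwise, and
#' every non-NAFLD subject is labelled normal/mild regardless of scores.
#' Two combined classifications accompany the three single methods:
#' `all3` (NASH only if all three scores positive — a serial/AND
#' combination) and `any1` (NASH if at least one positive — parallel/OR).
#'
#' @param cohort Cohort data.frame with gradable ultrasound for every
#'   subject (run [apply_exclusions()] first).
#' @param features Optional [derive_features()] output (recomputed if
#'   omitted).
#' @param thresholds See [nash_thresholds()].
#' @return data.frame (one row per subject): `hair_points`, `gholam_value`,
#'   `lfs_value`, the five logical NASH flags (`hair_nash`, `gholam_nash`,
#'   `lfs_nash`, `all3_nash`, `any1_nash`), `nafld`, and a 3-level factor
#'   `label_<method>` per classification scheme.
#' @export
classify_subjects <- function(cohort, features = NULL,
                              thresholds = nash_thresholds()) {
  grade <- cohort$ultrasound_grade
  if (any(is.na(grade) | grade %in% c("ungradable", "missing"))) {
    stop("ungradable or missing ultrasound grade; apply exclusions first")
  }
  if (is.null(features)) features <- derive_features(cohort, thresholds)
  nafld <- grade %in% c("moderate", "severe")
  hair <- hair_score(features$homa_ir, cohort$alt, cohort$systolic_bp,
                     cohort$diastolic_bp, cohort$htn_diagnosis,
                     cohort$htn_medication, thresholds)
  ghol <- gholam_score(cohort$ast, features$diabetes_gholam, thresholds)
  lfs <- nash_lfs(features$metabolic_syndrome, features$diabetes_lfs,
                  cohort$fasting_insulin, cohort$ast, cohort$alt, thresholds)
  panel <- data.frame(
    subject_id = cohort$subject_id,
    nafld = nafld,
    hair_points = hair$points, gholam_value = ghol$value, lfs_value = lfs$value,
    hair_nash = nafld & hair$positive,
    gholam_nash = nafld & ghol$positive,
    lfs_nash = nafld & lfs$positive,
    stringsAsFactors = FALSE)
  panel$all3_nash <- panel$hair_nash & panel$gholam_nash & panel$lfs_nash
  panel$any1_nash <- panel$hair_nash | panel$gholam_nash | panel$lfs_nash
  for (m in classification_schemes()) {
    flag <- panel[[paste0(m, "_nash")]]
    panel[[paste0("label_", m)]] <- factor(
      ifelse(flag, "nash", ifelse(nafld, "simple_nafld", "normal_mild")),
      levels = c("normal_mild", "simple_nafld", "nash"))
  }
  panel
}

#' The five classification schemes
#'
#' @return `c("hair", "gholam", "lfs", "all3", "any1")`.
#' @export
classification_schemes <- function() c("hair", "gholam", "lfs", "all3", "any1")
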