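test_that("HOMA-IR follows the Matthews normalization", {
  expect_equal(compute_homa_ir(90, 4.5), 1.0)
  expect_equal(compute_homa_ir(405, 1), 1.0)
  expect_equal(compute_homa_ir(126, 15), 126 * 15 / 405, tolerance = 1e-12)
  expect_error(compute_homa_ir(0, 5), "> 0")
})

test_that("HAIR points respect the published cutoffs and positivity rule", {
  all_high <- hair_score(6.0, 50, 150, 95, FALSE, FALSE)
  expect_identical(all_high$points, 3L)
  expect_true(all_high$positive)
  all_low <- hair_score(1.0, 10, 110, 70, FALSE, FALSE)
  expect_identical(all_low$points, 0L)
  expect_false(all_low$positive)
  # boundaries: HOMA-IR exactly 5 is not a point; DBP exactly 90 is
  edge <- hair_score(5.0, 41, 139, 90, FALSE, FALSE)
  expect_identical(edge$points, 2L)
  expect_true(edge$positive)
  # diagnosis or medication alone carries the blood-pressure point
  expect_identical(hair_score(1, 10, 110, 70, TRUE, FALSE)$points, 1L)
  expect_identical(hair_score(1, 10, 110, 70, FALSE, TRUE)$points, 1L)
})

test_that("Gholam score matches its closed form and inclusive cutoff", {
  expect_equal(gholam_score(1, FALSE)$value, 0)
  expect_false(gholam_score(1, FALSE)$positive)
  g <- gholam_score(50, TRUE)
  expect_equal(g$value, 2.627 * log(50) + 2.13, tolerance = 1e-12)
  expect_equal(g$value, 12.406884, tolerance = 1e-5)
  expect_true(g$positive)
  # positivity root: AST = exp(8.22/2.627) = 22.8521...
  near <- gholam_score(22.85, FALSE)
  expect_lt(abs(near$value - 8.22), 1e-3)
  expect_false(near$positive)  # 22.85 sits just below the root
  expect_true(gholam_score(22.86, FALSE)$positive)
  expect_error(gholam_score(0, FALSE), "> 0")
})

test_that("metabolic syndrome needs three of five criteria with sex-specific cuts", {
  expect_true(metabolic_syndrome(100, "male", 200, 35, 120, 70, FALSE, 90, FALSE))
  expect_false(metabolic_syndrome(90, "male", 100, 50, 118, 76, FALSE, 90, FALSE))
  # waist cutoff strict: 80.0 in a woman is not a criterion (here the
  # triglyceride and glucose criteria hold, so waist alone decides)
  expect_false(metabolic_syndrome(80, "female", 200, 55, 120, 70, FALSE, 105, FALSE))
  expect_true(metabolic_syndrome(80.1, "female", 200, 55, 120, 70, FALSE, 105, FALSE))
  # default blood-pressure rule needs both limbs; "or" rule is configurable
  expect_false(metabolic_syndrome(100, "male", 200, 45, 135, 70, FALSE, 90, FALSE))
  expect_true(metabolic_syndrome(100, "male", 200, 45, 135, 70, FALSE, 90, FALSE,
                                 thresholds = nash_thresholds(ms_bp_rule = "or")))
})

test_that("liver fat score matches hand arithmetic and codes diabetes as 0/2", {
  expect_equal(nash_lfs(FALSE, FALSE, 0, 20, 20)$value, -3.03, tolerance = 1e-12)
  expect_false(nash_lfs(FALSE, FALSE, 0, 20, 20)$positive)
  v <- nash_lfs(TRUE, TRUE, 20, 60, 30)
  expect_equal(v$value, 1.18 + 0.9 + 3.0 + 2.4 - 1.88 - 2.89, tolerance = 1e-12)
  expect_equal(v$value, 2.71, tolerance = 1e-12)
  expect_true(v$positive)
  expect_equal(nash_lfs(FALSE, FALSE, 0, 30, 30)$value, 0.04 * 30 - 0.94 - 2.89)
  expect_error(nash_lfs(FALSE, FALSE, 5, 20, 0), "> 0")
})

test_that("scores are monotone in their driving inputs", {
  ast <- seq(5, 200, by = 5)
  vals <- gholam_score(ast, FALSE)$value
  expect_true(all(diff(vals) > 0))
  ins <- seq(0, 50, by = 2.5)
  lv <- nash_lfs(FALSE, FALSE, ins, 30, 30)$value
  expect_true(all(diff(lv) > 0))
  expect_gt(nash_lfs(TRUE, FALSE, 10, 30, 30)$value,
            nash_lfs(FALSE, FALSE, 10, 30, 30)$value)
  expect_gt(nash_lfs(FALSE, TRUE, 10, 30, 30)$value,
            nash_lfs(FALSE, FALSE, 10, 30, 30)$value)
  for (h in c(1, 6)) for (a in c(10, 50)) {
    expect_gte(hair_score(h, a, 150, 95, FALSE, FALSE)$points,
               hair_score(h, a, 110, 70, FALSE, FALSE)$points)
  }
})

test_that("classification flags NASH only inside the NAFLD set", {
  # every score positive, but no moderate-to-severe steatosis
  rec <- make_record(ultrasound_grade = "none", fasting_insulin = 40,
                     fasting_glucose = 130, alt = 80, ast = 90,
                     systolic_bp = 150, diastolic_bp = 95, dm_diagnosis = TRUE)
  p <- classify_subjects(rec)
  expect_false(any(p$hair_nash, p$gholam_nash, p$lfs_nash))
  expect_true(all(p$label_hair == "normal_mild", p$label_gholam == "normal_mild"))
  p2 <- classify_subjects(make_record(ultrasound_grade = "severe",
                                      fasting_insulin = 40, fasting_glucose = 130,
                                      alt = 80, ast = 90, systolic_bp = 150,
                                      diastolic_bp = 95, dm_diagnosis = TRUE))
  expect_true(p2$all3_nash)
  expect_true(p2$any1_nash)
  expect_error(classify_subjects(make_record(ultrasound_grade = "ungradable")),
               "exclusions")
})

test_that("combined flags obey the boolean lattice on generated cohorts", {
  sc <- scored_cohort(3000, seed = 29)
  p <- classify_subjects(sc$cohort)
  expect_identical(p$all3_nash, p$hair_nash & p$gholam_nash & p$lfs_nash)
  expect_identical(p$any1_nash, p$hair_nash | p$gholam_nash | p$lfs_nash)
  expect_true(all(!p$all3_nash | p$any1_nash))
  n_each <- colSums(p[, c("hair_nash", "gholam_nash", "lfs_nash")])
  expect_true(all(sum(p$all3_nash) <= n_each & n_each <= sum(p$any1_nash)))
  # any flagged subject has moderate/severe steatosis
  flagged <- p$any1_nash
  expect_true(all(sc$cohort$ultrasound_grade[flagged] %in% c("moderate", "severe")))
  # exactly one label per method and consistency with the flags
  for (m in classification_schemes()) {
    lab <- p[[paste0("label_", m)]]
    expect_false(any(is.na(lab)))
    expect_identical(lab == "nash", p[[paste0(m, "_nash")]])
    expect_identical(lab == "simple_nafld",
                     p$nafld & !p[[paste0(m, "_nash")]])
  }
})

test_that("classification agrees with the brute-force oracle subject by subject", {
  sc <- scored_cohort(400, seed = 31)
  p <- classify_subjects(sc$cohort)
  o <- oracle_panel(sc$cohort)
  expect_identical(p$hair_nash, o$hair)
  expect_identical(p$gholam_nash, o$gholam)
  expect_identical(p$lfs_nash, o$lfs)
  expect_identical(as.character(p$label_hair), o$label_hair)
  expect_identical(as.character(p$label_gholam), o$label_gholam)
  expect_identical(as.character(p$label_lfs), o$label_lfs)
})

test_that("covariate categories resolve printed boundary overlaps as documented", {
  f <- categorize_covariates(make_record(total_cholesterol = 200))
  expect_equal(as.character(f$chol_cat), "normal")   # <= 200 normal
  expect_equal(as.character(categorize_covariates(
    make_record(total_cholesterol = 240))$chol_cat), "high")
  expect_equal(as.character(categorize_covariates(
    make_record(crp = 0.3))$crp_cat), "mild")        # 0.3 belongs to mild
  expect_equal(as.character(categorize_covariates(
    make_record(crp = 1.0))$crp_cat), "mild")
  expect_equal(as.character(categorize_covariates(
    make_record(c_peptide = 1.03))$c_peptide_cat), "normal")
  expect_equal(as.character(categorize_covariates(
    make_record(hei_score = 50))$hei_cat), "needs_improvement")
  # waist-hip risk: 0.84 in a woman is healthy, 0.85 at risk
  f2 <- categorize_covariates(make_record(sex = "female", waist_cm = 84, hip_cm = 100))
  expect_equal(as.character(f2$whr_risk), "healthy")
  f3 <- categorize_covariates(make_record(sex = "female", waist_cm = 85, hip_cm = 100))
  expect_equal(as.character(f3$whr_risk), "at_risk")
  # age groups and alcohol status
  expect_equal(as.character(categorize_covariates(make_record(age = 34L))$age_group), "20_34")
  expect_equal(as.character(categorize_covariates(make_record(age = 65L))$age_group), "65_plus")
  never <- categorize_covariates(make_record(ever_12_drinks_lifetime = FALSE,
                                             twelve_drinks_past_year = FALSE))
  expect_equal(as.character(never$alcohol_status), "never")
  former <- categorize_covariates(make_record(ever_12_drinks_lifetime = TRUE,
                                              twelve_drinks_past_year = FALSE))
  expect_equal(as.character(former$alcohol_status), "former")
})

test_that("score-specific diabetes definitions stay distinct at glucose 126", {
  f <- derive_features(make_record(fasting_glucose = 126))
  expect_false(f$diabetes_gholam)  # strict > 126
  expect_true(f$diabetes_lfs)     # inclusive >= 126
  f2 <- derive_features(make_record(fasting_glucose = 100, two_hr_glucose = 205))
  expect_true(f2$diabetes_lfs)
  expect_false(f2$diabetes_gholam)
})

test_that("threshold overrides propagate through classification", {
  rec <- make_record(ultrasound_grade = "moderate", ast = 20)
  # 2.627 * ln(20) = 7.87, below the default 8.22 cutoff
  expect_false(classify_subjects(rec)$gholam_nash)
  lowered <- classify_subjects(rec, thresholds = nash_thresholds(gholam_cutoff = 7.8))
  expect_true(lowered$gholam_nash)
  expect_error(nash_thresholds(not_a_threshold = 1), "unknown")
})
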