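# One-row cohort builder with clinically unremarkable defaults; override any
# field by name.
make_record <- function(...) {
  rec <- data.frame(
    subject_id = "S1", age = 45L, sex = "male", race_ethnicity = "white",
    education = "hs", poverty_ratio = 2.5, urbanization = "urban",
    birthplace = "us", years_in_us = "entire_life", smoking = "never",
    alcohol_days_per_year = 52L, alcohol_drinks_per_day = 1,
    ever_12_drinks_lifetime = TRUE, twelve_drinks_past_year = TRUE,
    activity_level = "meets_guidelines", waist_cm = 90, hip_cm = 100,
    systolic_bp = 118, diastolic_bp = 76, htn_diagnosis = FALSE,
    htn_medication = FALSE, dm_diagnosis = FALSE, fasting_glucose = 90,
    two_hr_glucose = 110, fasting_insulin = 8, c_peptide = 0.6, alt = 22,
    ast = 20, total_cholesterol = 190, hdl = 50, triglyceride = 110,
    crp = 0.2, hba1c = 5.3, transferrin_saturation = 28,
    hbsag_positive = FALSE, anti_hbc_positive = FALSE,
    hcv_ab_positive = FALSE, hcv_rna_positive = FALSE,
    steatogenic_medication = FALSE, hei_score = 70,
    ultrasound_grade = "none", stratum = "ST01", psu = "PSU1", weight = 1,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_cohort <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) make_record(subject_id = paste0("S", i), ...)))
}

# Independent brute-force transcription of the three scoring systems and the
# three-class assignment, written subject by subject with no shared code with
# the package implementation. Used as the scoring oracle.
oracle_panel <- function(cohort) {
  out <- data.frame(hair = logical(nrow(cohort)), gholam = logical(nrow(cohort)),
                    lfs = logical(nrow(cohort)))
  labs <- list()
  for (i in seq_len(nrow(cohort))) {
    r <- cohort[i, ]
    nafld <- r$ultrasound_grade %in% c("moderate", "severe")

    homa <- r$fasting_glucose * r$fasting_insulin / 405
    htn <- (r$systolic_bp >= 140) || (r$diastolic_bp >= 90) ||
      isTRUE(r$htn_diagnosis) || isTRUE(r$htn_medication)
    hair_pts <- (homa > 5) + (r$alt > 40) + htn
    hair_pos <- hair_pts >= 2

    dm_ghol <- isTRUE(r$dm_diagnosis) || (r$fasting_glucose > 126)
    ghol_val <- 2.627 * log(r$ast) + ifelse(dm_ghol, 2.13, 0)
    ghol_pos <- ghol_val >= 8.22

    waist_crit <- if (r$sex == "male") r$waist_cm > 94 else r$waist_cm > 80
    hdl_crit <- if (r$sex == "male") r$hdl < 40 else r$hdl < 50
    bp_crit <- (r$systolic_bp >= 130 && r$diastolic_bp >= 85) || isTRUE(r$htn_medication)
    glu_crit <- (r$fasting_glucose >= 100) || isTRUE(r$dm_diagnosis)
    ms <- sum(waist_crit, r$triglyceride >= 150, hdl_crit, bp_crit, glu_crit) >= 3
    dm_lfs <- isTRUE(r$dm_diagnosis) || (r$fasting_glucose >= 126) ||
      (!is.na(r$two_hr_glucose) && r$two_hr_glucose >= 200)
    lfs_val <- 1.18 * ms + 0.45 * (2 * dm_lfs) + 0.15 * r$fasting_insulin +
      0.04 * r$ast - 0.94 * (r$ast / r$alt) - 2.89
    lfs_pos <- lfs_val >= 2.122

    out$hair[i] <- nafld && hair_pos
    out$gholam[i] <- nafld && ghol_pos
    out$lfs[i] <- nafld && lfs_pos
    for (m in c("hair", "gholam", "lfs")) {
      flag <- out[[m]][i]
      labs[[m]][i] <- if (flag) "nash" else if (nafld) "simple_nafld" else "normal_mild"
    }
  }
  out$all3 <- out$hair & out$gholam & out$lfs
  out$any1 <- out$hair | out$gholam | out$lfs
  out$label_hair <- labs$hair; out$label_gholam <- labs$gholam
  out$label_lfs <- labs$lfs
  out
}

# A generated cohort restricted to gradable-ultrasound, complete-case rows;
# convenient input for scoring and survey tests.
scored_cohort <- function(n, seed, ...) {
  sim <- generate_cohort(cohort_config(n_subjects = n, seed = seed,
                                       missingness_rate = 0, ...))
  keep <- !sim$cohort$ultrasound_grade %in% c("ungradable", "missing")
  list(cohort = sim$cohort[keep, ], latent = sim$latent[keep])
}
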