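#' Configuration for the synthetic-cohort generator
#'
#' Describes an NHANES-like synthetic population: a three-level latent liver
#' state (no-to-mild steatosis, simple NAFLD, NASH), covariate effects on the
#' latent NASH odds, and a stratified multi-PSU sampling design with unequal
#' weights. The defaults are the study conditions used throughout the test
#' suite and the simulation studies in the vignette.
#'
#' @param n_subjects Number of subjects to generate.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration and seed.
#' @param latent_prevalence Named probabilities over
#'   `c(normal_mild, simple_nafld, nash)`; must sum to 1.
#' @param effect_or Named positive numerics giving odds ratios on the latent
#'   NASH-versus-normal scale. Names are `"column:level"` for categorical
#'   contrasts (e.g. `"race_ethnicity:mexican_american"`) or a bare logical
#'   column name. Intercepts are recalibrated so the marginal latent
#'   prevalences still match `latent_prevalence`.
#' @param n_strata Number of design strata.
#' @param psus_per_stratum PSUs per stratum (at least 2, as design-based
#'   variance estimation requires).
#' @param weight_cv Coefficient of variation of the log-normal sampling
#'   weights (normalized to mean 1); 0 gives equal weights.
#' @param missingness_rate Per-field probability of a missing value in the
#'   optional (non-score) fields.
#' @param misgrading_rate Probability that ultrasound grading crosses the
#'   none-mild / moderate-severe boundary in the wrong direction.
#' @param ungradable_rate Probability of an ungradable or missing ultrasound.
#' @return A validated list of class `"cohort_config"`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 10000L,
                          seed = 1L,
                          latent_prevalence = c(normal_mild = 0.80,
                                                simple_nafld = 0.12,
                                                nash = 0.08),
                          effect_or = c("race_ethnicity:mexican_american" = 1.6,
                                        "smoking:current" = 1.4,
                                        "urbanization:rural" = 1.3),
                          n_strata = 15L,
                          psus_per_stratum = 2L,
                          weight_cv = 0.5,
                          missingness_rate = 0.02,
                          misgrading_rate = 0.02,
                          ungradable_rate = 0.01) {
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              latent_prevalence = latent_prevalence, effect_or = effect_or,
              n_strata = as.integer(n_strata),
              psus_per_stratum = as.integer(psus_per_stratum),
              weight_cv = weight_cv, missingness_rate = missingness_rate,
              misgrading_rate = misgrading_rate,
              ungradable_rate = ungradable_rate)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  lp <- cfg$latent_prevalence
  want <- c("normal_mild", "simple_nafld", "nash")
  if (is.null(names(lp)) || !setequal(names(lp), want)) {
    stop("latent_prevalence must be named over normal_mild, simple_nafld, nash")
  }
  lp <- lp[want]
  if (any(lp < 0 | lp > 1) || abs(sum(lp) - 1) > 1e-12) {
    stop("latent_prevalence entries must lie in [0,1] and sum to 1")
  }
  if (cfg$n_subjects < 1L) stop("n_subjects must be positive")
  if (cfg$psus_per_stratum < 2L) {
    stop("psus_per_stratum must be >= 2 (variance estimation needs >= 2 PSUs per stratum)")
  }
  if (cfg$n_strata < 1L) stop("n_strata must be positive")
  if (length(cfg$effect_or) && any(cfg$effect_or <= 0)) {
    stop("all effect_or values must be > 0")
  }
  if (cfg$n_subjects < cfg$n_strata * cfg$psus_per_stratum) {
    stop("n_subjects too small to populate every (stratum, psu) cell")
  }
  for (fld in c("weight_cv", "missingness_rate", "misgrading_rate",
                "ungradable_rate")) {
    if (cfg[[fld]] < 0) stop(fld, " must be non-negative")
  }
  invisible(cfg)
}

#' Generate a synthetic NHANES-like cohort
#'
#' Draws covariates, assigns a three-level latent liver state by a
#' multinomial-logit model (intercepts calibrated so the marginal latent
#' prevalences match the configuration, covariate effects on the NASH
#' equation as configured), and then draws laboratory and clinical values
#' from class-conditional Gaussian / log-normal distributions whose
#' score-relevant tails (fasting insulin, glucose, AST, ALT, blood pressure,
#' waist) shift with the latent state — so each of the three NASH scores has
#' sensitivity and specificity strictly between 0 and 1 against the latent
#' label. Ultrasound grade is moderate/severe for latent NAFLD/NASH subjects
#' and none/mild for latent normal subjects, apart from a configurable
#' misgrading rate. Subjects are spread over a stratified multi-PSU design
#' with log-normal weights normalized to mean 1.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"synthetic_cohort"` with elements `cohort`
#'   (validated cohort data.frame) and `latent` (factor of true liver
#'   states, levels `normal_mild`, `simple_nafld`, `nash`).
#' @examples
#' sim <- generate_cohort(cohort_config(n_subjects = 500, seed = 42))
#' table(sim$latent)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- config$n_subjects

  d <- list(subject_id = sprintf("S%06d", seq_len(n)))
  d$age <- sample(20:74, n, replace = TRUE)
  d$sex <- sample(c("male", "female"), n, TRUE, c(0.48, 0.52))
  d$race_ethnicity <- sample(c("white", "black", "mexican_american", "other"),
                             n, TRUE, c(0.74, 0.11, 0.06, 0.09))
  d$education <- sample(c("lt_hs", "hs", "gt_hs"), n, TRUE, c(0.25, 0.35, 0.40))
  d$poverty_ratio <- round(pmin(stats::rlnorm(n, log(2), 0.6), 8.5), 2)
  d$urbanization <- sample(c("urban", "rural"), n, TRUE, c(0.75, 0.25))
  d$birthplace <- sample(c("us", "mexico", "other"), n, TRUE, c(0.90, 0.04, 0.06))
  d$years_in_us <- ifelse(d$birthplace == "us", "entire_life",
                          sample(c("lt5", "5to10", "gt10"), n, TRUE,
                                 c(0.2, 0.25, 0.55)))
  d$smoking <- sample(c("never", "former", "current"), n, TRUE,
                      c(0.50, 0.25, 0.25))
  d$ever_12_drinks_lifetime <- stats::runif(n) < 0.70
  d$twelve_drinks_past_year <- d$ever_12_drinks_lifetime & (stats::runif(n) < 0.60)
  drinker <- d$twelve_drinks_past_year
  d$alcohol_days_per_year <- ifelse(drinker,
                                    pmax(1L, as.integer(round(365 * stats::rbeta(n, 1.2, 4)))),
                                    0L)
  d$alcohol_drinks_per_day <- ifelse(d$alcohol_days_per_year > 0,
                                     round(stats::rlnorm(n, log(1.5), 0.6), 2), 0)
  d$activity_level <- sample(c("inactive", "below_guidelines", "meets_guidelines"),
                             n, TRUE, c(0.30, 0.35, 0.35))
  d$hei_score <- round(pmin(100, pmax(0, stats::rnorm(n, 65, 12))), 1)

  latent <- draw_latent_state(d, config)
  k <- as.integer(latent)  # 1 normal_mild, 2 simple_nafld, 3 nash

  pick <- function(v) v[k]
  male <- d$sex == "male"
  d$fasting_insulin <- round(stats::rlnorm(n, pick(c(2.0, 2.5, 3.0)), 0.45), 1)
  d$fasting_glucose <- round(pmax(55, stats::rnorm(n, pick(c(92, 100, 112)),
                                                   pick(c(10, 14, 28)))), 1)
  d$two_hr_glucose <- round(pmax(50, 1.2 * d$fasting_glucose +
                                   stats::rnorm(n, 0, 25)), 1)
  d$alt <- round(stats::rlnorm(n, pick(log(c(18, 28, 48))), 0.40), 1)
  d$ast <- round(d$alt * stats::rlnorm(n, pick(log(c(1.05, 0.95, 0.90))), 0.25), 1)
  d$systolic_bp <- round(pmax(80, stats::rnorm(n, pick(c(118, 124, 132)), 14)))
  d$diastolic_bp <- round(pmax(45, stats::rnorm(n, pick(c(74, 78, 83)), 9)))
  d$htn_diagnosis <- stats::runif(n) < pick(c(0.12, 0.20, 0.30))
  d$htn_medication <- d$htn_diagnosis & (stats::runif(n) < 0.70)
  d$dm_diagnosis <- stats::runif(n) < pick(c(0.04, 0.09, 0.20))
  d$waist_cm <- round(pmax(55, stats::rnorm(
    n,
    ifelse(male, pick(c(94, 100, 106)), pick(c(82, 90, 98))),
    ifelse(male, 10, 11))), 1)
  whr_true <- pmax(0.6, stats::rnorm(
    n,
    ifelse(male, pick(c(0.92, 0.95, 0.98)), pick(c(0.83, 0.87, 0.91))),
    0.05))
  d$hip_cm <- round(d$waist_cm / whr_true, 1)
  d$triglyceride <- round(stats::rlnorm(n, pick(log(c(110, 140, 175))), 0.45))
  d$hdl <- round(pmax(15, stats::rnorm(
    n, ifelse(male, pick(c(46, 43, 40)), pick(c(56, 52, 48))), 11)))
  d$total_cholesterol <- round(pmax(90, stats::rnorm(n, pick(c(200, 208, 215)), 38)))
  d$crp <- round(stats::rlnorm(n, pick(log(c(0.18, 0.28, 0.45))), 0.8), 2)
  d$c_peptide <- round(stats::rlnorm(n, pick(log(c(0.55, 0.75, 1.00))), 0.40), 2)
  d$hba1c <- round(pmax(3.5, stats::rnorm(n, pick(c(5.3, 5.6, 6.1)),
                                          pick(c(0.4, 0.5, 0.9)))), 1)

  d$transferrin_saturation <- round(pmax(2, stats::rnorm(n, 28, 9)), 1)
  d$hbsag_positive <- stats::runif(n) < 0.010
  d$anti_hbc_positive <- d$hbsag_positive | (stats::runif(n) < 0.050)
  d$hcv_ab_positive <- stats::runif(n) < 0.017
  d$hcv_rna_positive <- d$hcv_ab_positive & (stats::runif(n) < 0.75)
  d$steatogenic_medication <- stats::runif(n) < 0.010

  nafld <- k >= 2L
  grade <- ifelse(nafld,
                  sample(c("moderate", "severe"), n, TRUE, c(0.75, 0.25)),
                  sample(c("none", "mild"), n, TRUE, c(0.70, 0.30)))
  mis <- stats::runif(n) < config$misgrading_rate
  grade[mis & nafld] <- "mild"
  grade[mis & !nafld] <- "moderate"
  ungr <- stats::runif(n) < config$ungradable_rate
  grade[ungr] <- sample(c("ungradable", "missing"), n, TRUE)[ungr]
  d$ultrasound_grade <- grade

  cells <- expand.grid(stratum = sprintf("ST%02d", seq_len(config$n_strata)),
                       psu = sprintf("PSU%d", seq_len(config$psus_per_stratum)),
                       stringsAsFactors = FALSE)
  idx <- c(seq_len(nrow(cells)),
           sample(nrow(cells), n - nrow(cells), replace = TRUE))
  idx <- sample(idx)  # shuffle so cell guarantees are not positional
  d$stratum <- cells$stratum[idx]
  d$psu <- cells$psu[idx]
  if (config$weight_cv > 0) {
    sdl <- sqrt(log(1 + config$weight_cv^2))
    w <- stats::rlnorm(n, -sdl^2 / 2, sdl)
    d$weight <- round(w / mean(w), 6)
  } else {
    d$weight <- rep(1, n)
  }

  cohort <- as.data.frame(d, stringsAsFactors = FALSE)
  if (config$missingness_rate > 0) {
    optional <- cohort_schema()$column[!cohort_schema()$required]
    for (col in optional) {
      cohort[[col]][stats::runif(n) < config$missingness_rate] <- NA
    }
  }
  validate_cohort(cohort)
  out <- list(cohort = cohort, latent = latent, config = config)
  class(out) <- "synthetic_cohort"
  out
}

# Latent liver state by multinomial logit with the NASH equation carrying the
# configured covariate odds ratios; intercepts calibrated by iterative
# proportional adjustment so the marginal class probabilities hit the target.
draw_latent_state <- function(d, config) {
  n <- length(d$subject_id)
  lp <- config$latent_prevalence[c("normal_mild", "simple_nafld", "nash")]
  eta_nash <- rep(0, n)
  for (nm in names(config$effect_or)) {
    b <- log(config$effect_or[[nm]])
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (!parts[1] %in% names(d)) stop("effect_or refers to unknown column: ", parts[1])
      eta_nash <- eta_nash + b * (d[[parts[1]]] == parts[2])
    } else {
      if (!nm %in% names(d)) stop("effect_or refers to unknown column: ", nm)
      eta_nash <- eta_nash + b * as.numeric(d[[nm]])
    }
  }
  a <- log(pmax(lp[2:3], 1e-12) / max(lp[1], 1e-12))  # starting intercepts
  for (it in 1:200) {
    e2 <- exp(a[1])
    e3 <- exp(a[2] + eta_nash)
    den <- 1 + e2 + e3
    pbar <- c(mean(e2 / den), mean(e3 / den))
    if (max(abs(pbar - lp[2:3])) < 1e-12) break
    a <- a + log(lp[2:3] / pbar)
  }
  p2 <- exp(a[1]) / (1 + exp(a[1]) + exp(a[2] + eta_nash))
  p3 <- exp(a[2] + eta_nash) / (1 + exp(a[1]) + exp(a[2] + eta_nash))
  u <- stats::runif(n)
  k <- 1L + (u < p2 + p3) + (u < p3)  # nash first in the cumulative order
  factor(c("normal_mild", "simple_nafld", "nash")[k],
         levels = c("normal_mild", "simple_nafld", "nash"))
}
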