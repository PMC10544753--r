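#' Pipeline run configuration
#'
#' Bundles every choice a full analysis run needs: exactly one input source
#' (a CSV path or a synthetic-cohort configuration), threshold overrides,
#' the listwise-deletion field set, the standard population for age
#' adjustment, the regression covariates, the output directory and the
#' seed. Configurations can also be loaded from a YAML file with
#' [read_run_config()].
#'
#' @param csv Path to a cohort CSV (mutually exclusive with `synthetic`).
#' @param dialect Optional column-name map for [read_cohort()].
#' @param synthetic A [cohort_config()] (mutually exclusive with `csv`).
#' @param thresholds Named list of [nash_thresholds()] overrides.
#' @param required_fields Columns for listwise deletion.
#' @param std_population `"us2000"`, `"us1990"`, or a CSV path.
#' @param covariates Covariate columns for the risk-factor regressions
#'   (columns of the cohort or of [derive_features()]).
#' @param out_dir Output directory.
#' @param seed Integer seed governing all randomness of the run.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(csv = NULL, dialect = NULL, synthetic = NULL,
                       thresholds = list(),
                       required_fields = default_required_fields(),
                       std_population = "us2000",
                       covariates = c("age_group", "sex", "race_ethnicity",
                                      "whr_risk", "smoking"),
                       out_dir = tempfile("nashscreen_run_"),
                       seed = 1L) {
  if (is.null(csv) == is.null(synthetic)) {
    stop("specify exactly one input source: csv or synthetic")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "cohort_config")) {
    stop("synthetic must be a cohort_config()")
  }
  structure(list(csv = csv, dialect = dialect, synthetic = synthetic,
                 thresholds = thresholds, required_fields = required_fields,
                 std_population = std_population, covariates = covariates,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `synthetic`
#' mapping is passed to [cohort_config()]. The run seed, when given,
#' overrides the synthetic generator seed so that one seed governs the run.
#'
#' @param path YAML file path.
#' @param seed Optional seed override.
#' @param out_dir Optional output-directory override.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, seed = NULL, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(y$synthetic)) {
    if (!is.null(y$seed)) y$synthetic$seed <- y$seed
    if (!is.null(y$synthetic$latent_prevalence)) {
      y$synthetic$latent_prevalence <- unlist(y$synthetic$latent_prevalence)
    }
    if (!is.null(y$synthetic$effect_or)) {
      y$synthetic$effect_or <- unlist(y$synthetic$effect_or)
    }
    y$synthetic <- do.call(cohort_config, y$synthetic)
  }
  if (!is.null(y$dialect)) y$dialect <- unlist(y$dialect)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes generate/read, eligibility exclusions, feature derivation,
#' score classification, screening-performance composition, and the
#' design-weighted statistical stage, writing a machine-readable report
#' bundle to the configured output directory:
#'
#' * `exclusion_tally.json`, `flow.txt` — the participant-flow audit;
#' * `score_panel.csv` — per-subject scores, flags and 3-class labels;
#' * `prevalence.csv` — crude, weighted (with SE/CI) and age-standardized
#'   NASH prevalence for the five classification schemes;
#' * `net_performance.tsv` — serial/parallel composition of the published
#'   single-method sensitivities and specificities;
#' * `regression_<scheme>.tsv` — OR/AOR risk-factor tables per scheme;
#' * `manifest.json` — config hash, seed and package version.
#'
#' Identical configuration and seed give byte-identical numeric output.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `exclusions`, `features`, `panel`, `prevalence`, `net_performance`,
#'   `regressions`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # --- input stage -------------------------------------------------------
  if (!is.null(config$synthetic)) {
    sim <- generate_cohort(config$synthetic)
    cohort <- sim$cohort
  } else {
    cohort <- with_stage("read_cohort", read_cohort(config$csv, config$dialect))
  }

  # --- eligibility -------------------------------------------------------
  excl <- with_stage("apply_exclusions",
                     suppressWarnings(apply_exclusions(cohort, config$required_fields)))
  paths$tally <- file.path(config$out_dir, "exclusion_tally.json")
  exclusion_tally_json(excl, paths$tally)
  paths$flow <- file.path(config$out_dir, "flow.txt")
  writeLines(format_flow_report(excl), paths$flow)
  analysis <- excl$cohort

  # --- scoring -----------------------------------------------------------
  th <- do.call(nash_thresholds, config$thresholds)
  features <- with_stage("derive_features", derive_features(analysis, th))
  panel <- with_stage("classify_subjects", classify_subjects(analysis, features, th))
  paths$panel <- file.path(config$out_dir, "score_panel.csv")
  utils::write.csv(panel, paths$panel, row.names = FALSE, na = "")

  # --- screening math ----------------------------------------------------
  paths$netperf <- file.path(config$out_dir, "net_performance.tsv")
  netperf <- net_performance_table(paths$netperf)

  # --- survey statistics -------------------------------------------------
  design <- with_stage("survey_design", cohort_design(analysis))
  std <- standard_population(config$std_population)
  prevalence <- with_stage("prevalence_table",
                           prevalence_table(panel, features, design, std))
  stopifnot(all(prevalence$weighted[prevalence$scheme == "all3"] <=
                  prevalence$weighted + 1e-12),
            all(prevalence$weighted <=
                  prevalence$weighted[prevalence$scheme == "any1"] + 1e-12))
  paths$prevalence <- file.path(config$out_dir, "prevalence.csv")
  utils::write.csv(prevalence, paths$prevalence, row.names = FALSE)

  reg_data <- cbind(analysis, features,
                    panel[, grep("^label_", names(panel))])
  regressions <- list()
  for (scheme in classification_schemes()) {
    fit_tab <- with_stage(paste0("regression_", scheme),
      or_aor_table(paste0("label_", scheme), config$covariates, reg_data, design))
    p <- file.path(config$out_dir, sprintf("regression_%s.tsv", scheme))
    utils::write.table(fit_tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths[[paste0("regression_", scheme)]] <- p
    regressions[[scheme]] <- fit_tab
  }

  # --- manifest ----------------------------------------------------------
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(config_hash = unname(tools::md5sum(tmp)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("nashscreen")))
  unlink(tmp)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             paths$manifest)

  invisible(list(cohort = cohort, exclusions = excl, features = features,
                 panel = panel, prevalence = prevalence,
                 net_performance = netperf, regressions = regressions,
                 design = design, paths = paths))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Crude, weighted and age-standardized NASH prevalence per scheme
#'
#' @param panel [classify_subjects()] output.
#' @param features [derive_features()] output (for the age groups).
#' @param design A [survey_design()] aligned with the panel.
#' @param std Standard-population proportions (see [standard_population()]).
#' @return data.frame, one row per classification scheme: `crude`,
#'   `weighted`, `se`, `ci_low`, `ci_high`, `age_standardized`.
#' @export
prevalence_table <- function(panel, features, design, std) {
  rows <- lapply(classification_schemes(), function(scheme) {
    flag <- panel[[paste0(scheme, "_nash")]]
    est <- weighted_prevalence(flag, design)
    grp <- as.character(features$age_group)
    gp <- vapply(names(std), function(g) {
      idx <- !is.na(grp) & grp == g
      if (!any(idx)) return(NA_real_)
      w <- design$weight[idx]
      sum(w * flag[idx]) / sum(w)
    }, numeric(1))
    data.frame(scheme = scheme,
               crude = mean(flag),
               weighted = est$estimate, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               age_standardized = direct_standardize(gp, std),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
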