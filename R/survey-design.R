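#' Complex-survey design
#'
#' Stratified multi-PSU design with per-subject sampling weights; the basis
#' for all design-based variance estimation in the package (Taylor
#' linearization with PSUs as first-stage units, with-replacement
#' approximation, as documented for NHANES). Design degrees of freedom are
#' `#PSUs - #strata`.
#'
#' @param stratum,psu Per-subject design labels; PSU labels are nested
#'   within stratum.
#' @param weight Positive per-subject sampling weights.
#' @return List of class `"survey_design"` with `stratum`, `psu`, `weight`,
#'   `df`.
#' @export
survey_design <- function(stratum, psu, weight) {
  n <- length(weight)
  if (length(stratum) != n || length(psu) != n) {
    stop("stratum, psu and weight must have equal length")
  }
  if (any(is.na(weight) | weight <= 0)) stop("weights must be positive")
  if (any(is.na(stratum) | is.na(psu))) stop("stratum and psu must be non-missing")
  stratum <- as.character(stratum)
  psu <- paste(stratum, as.character(psu), sep = "\r")  # nest PSU in stratum
  n_psu_per_stratum <- tapply(psu, stratum, function(x) length(unique(x)))
  if (any(n_psu_per_stratum < 2)) {
    stop("every stratum needs >= 2 PSUs for variance estimation; offending: ",
         paste(names(n_psu_per_stratum)[n_psu_per_stratum < 2], collapse = ", "))
  }
  df <- length(unique(psu)) - length(unique(stratum))
  structure(list(stratum = stratum, psu = psu, weight = weight, df = df),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("survey design: %d subjects, %d strata, %d PSUs, df = %d\n",
              length(x$weight), length(unique(x$stratum)),
              length(unique(x$psu)), x$df))
  invisible(x)
}

#' Build a survey design from cohort columns
#'
#' @param cohort Cohort data.frame with `stratum`, `psu`, `weight` columns.
#' @return A [survey_design()].
#' @export
cohort_design <- function(cohort) {
  survey_design(cohort$stratum, cohort$psu, cohort$weight)
}

# Design-based covariance of totals of per-unit contributions.
# z: n x p matrix of (already weighted) per-unit contributions to p totals.
# Taylor linearization, with-replacement first stage:
#   v = sum_h n_h/(n_h - 1) * sum_j (t_hj - tbar_h)(t_hj - tbar_h)'
# where t_hj are PSU totals within stratum h.
linearized_total_vcov <- function(z, design) {
  z <- as.matrix(z)
  p <- ncol(z)
  v <- matrix(0, p, p)
  for (h in unique(design$stratum)) {
    in_h <- design$stratum == h
    zt <- rowsum(z[in_h, , drop = FALSE], design$psu[in_h])
    nh <- nrow(zt)
    centered <- sweep(zt, 2, colMeans(zt))
    v <- v + nh / (nh - 1) * crossprod(centered)
  }
  v
}

#' Design-weighted prevalence with linearized variance
#'
#' Ratio estimator `sum(w * flag) / sum(w)` with Taylor-linearized
#' design-based standard error over strata and PSUs. The confidence
#' interval is computed on the logit scale with a t quantile on the design
#' degrees of freedom and back-transformed, which keeps it inside \[0,1\];
#' degenerate prevalences of exactly 0 or 1 get a zero-width interval.
#'
#' @param flags Logical (or 0/1) vector, one element per subject.
#' @param design A [survey_design()] aligned with `flags`.
#' @param level Confidence level.
#' @return List of class `"survey_estimate"`: `estimate`, `se`, `ci_low`,
#'   `ci_high`, `df`, `n`.
#' @export
weighted_prevalence <- function(flags, design, level = 0.95) {
  flags <- as.numeric(flags)
  if (length(flags) != length(design$weight)) {
    stop("flags and design must be aligned")
  }
  if (any(is.na(flags))) stop("flags must be non-missing (listwise-delete first)")
  w <- design$weight
  p <- sum(w * flags) / sum(w)
  # linearized contribution of unit i to the ratio
  z <- w * (flags - p) / sum(w)
  se <- sqrt(drop(linearized_total_vcov(cbind(z), design)))
  ci <- prevalence_ci(p, se, design$df, level)
  structure(list(estimate = p, se = se, ci_low = ci[1], ci_high = ci[2],
                 df = design$df, n = length(flags)),
            class = "survey_estimate")
}

prevalence_ci <- function(p, se, df, level) {
  if (p <= 0 || p >= 1 || se == 0) return(c(p, p))
  tq <- stats::qt(1 - (1 - level) / 2, df)
  l <- stats::qlogis(p)
  se_l <- se / (p * (1 - p))
  stats::plogis(c(l - tq * se_l, l + tq * se_l))
}

#' @export
print.survey_estimate <- function(x, ...) {
  cat(sprintf("estimate %.4f (SE %.4f, 95%% CI %.4f-%.4f, df %d)\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$df))
  invisible(x)
}

#' Directly age-standardized prevalence
#'
#' Weights age-group-specific prevalences by a fixed standard population's
#' age distribution: `sum_g std_g * prev_g`. The result always lies between
#' the smallest and largest group prevalence.
#'
#' @param group_prevalence Named numeric vector of per-age-group prevalences.
#' @param std Named numeric vector of standard-population proportions over
#'   the same age groups (non-negative, summing to 1).
#' @return The standardized prevalence.
#' @examples
#' direct_standardize(c(a = 0.02, b = 0.04), c(a = 0.5, b = 0.5)) # 0.03
#' @export
direct_standardize <- function(group_prevalence, std) {
  if (is.null(names(group_prevalence)) || is.null(names(std)) ||
      !setequal(names(group_prevalence), names(std))) {
    stop("group_prevalence and std must be named over the same age groups")
  }
  std <- std[names(group_prevalence)]
  if (any(std < 0) || abs(sum(std) - 1) > 1e-12) {
    stop("standard proportions must be non-negative and sum to 1")
  }
  sum(std * group_prevalence)
}

#' Bundled standard populations
#'
#' Age distributions over the four analysis age groups (20–34, 35–49,
#' 50–64, 65–74) for direct standardization: the year-2000 projected US
#' standard population and the 1990 US census population, each renormalized
#' to the 20–74 range. These are approximations assembled from published
#' census age tables at 5-year resolution.
#'
#' @param which `"us2000"` or `"us1990"`, or a path to a 2-column CSV
#'   (`age_group`, `proportion`).
#' @return Named numeric vector of proportions summing to 1.
#' @export
standard_population <- function(which = c("us2000", "us1990")) {
  if (length(which) == 1L && file.exists(which)) {
    tab <- utils::read.csv(which, stringsAsFactors = FALSE)
  } else {
    which <- match.arg(which)
    path <- system.file("extdata", paste0("std_pop_", which, ".csv"),
                        package = "nashscreen", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  std <- stats::setNames(tab$proportion, tab$age_group)
  std / sum(std)
}

#' Rao-Scott adjusted chi-squared test of association
#'
#' Pearson chi-squared test of independence on the design-weighted
#' contingency table with a first-order Rao-Scott correction: the Pearson
#' statistic computed from weighted proportions is divided by the mean
#' generalized design effect, estimated from the Taylor-linearized design
#' effects of the cell and marginal proportions. With equal weights and an
#' each-subject-its-own-PSU design the correction factor is 1 and the
#' statistic reduces to the classical Pearson value. Levels absent after
#' weighting are collapsed away with a warning.
#'
#' @param rows,cols Factors (or vectors) of row/column categories.
#' @param design A [survey_design()] aligned with them.
#' @param correction `FALSE` gives the uncorrected Pearson statistic on the
#'   weighted table.
#' @return List of class `"svy_chisq"`: `statistic`, `df`, `p_value`,
#'   `delta_bar` (mean design effect used).
#' @export
rao_scott_chi2 <- function(rows, cols, design, correction = TRUE) {
  keep <- !is.na(rows) & !is.na(cols)
  if (!all(keep)) stop("rows and cols must be non-missing (listwise-delete first)")
  rows <- factor(rows); cols <- factor(cols)
  if (any(table(rows) == 0) || any(table(cols) == 0)) {
    warning("empty categories collapsed before testing")
    rows <- droplevels(rows); cols <- droplevels(cols)
  }
  R <- nlevels(rows); C <- nlevels(cols)
  if (R < 2 || C < 2) stop("need at least two levels in each dimension")
  n <- length(rows)
  w <- design$weight
  W <- sum(w)
  # weighted cell and marginal proportions
  p_rc <- as.matrix(stats::xtabs(w ~ rows + cols)) / W
  p_r <- rowSums(p_rc); p_c <- colSums(p_rc)
  expected <- outer(p_r, p_c)
  if (any(expected == 0)) {
    warning("empty weighted margins collapsed before testing")
    keep_r <- p_r > 0; keep_c <- p_c > 0
    p_rc <- p_rc[keep_r, keep_c, drop = FALSE]
    p_rc <- p_rc / sum(p_rc)
    p_r <- rowSums(p_rc); p_c <- colSums(p_rc)
    expected <- outer(p_r, p_c)
    R <- nrow(p_rc); C <- ncol(p_rc)
  }
  x2 <- n * sum((p_rc - expected)^2 / expected)
  df <- as.integer((R - 1) * (C - 1))
  delta_bar <- 1
  if (correction) {
    deff <- function(ind, p) {
      # design variance of a weighted proportion vs binomial p(1-p)/(n-1)
      if (p <= 0 || p >= 1) return(1)
      z <- w * (ind - p) / W
      v <- drop(linearized_total_vcov(cbind(z), design))
      v / (p * (1 - p) / (n - 1))
    }
    d_rc <- matrix(0, R, C); d_r <- numeric(R); d_c <- numeric(C)
    for (i in seq_len(R)) {
      for (j in seq_len(C)) {
        d_rc[i, j] <- deff(rows == levels(rows)[i] & cols == levels(cols)[j],
                           p_rc[i, j])
      }
      d_r[i] <- deff(rows == levels(rows)[i], p_r[i])
    }
    for (j in seq_len(C)) d_c[j] <- deff(cols == levels(cols)[j], p_c[j])
    num <- sum((1 - p_rc) * d_rc) - sum((1 - p_r) * d_r) - sum((1 - p_c) * d_c)
    delta_bar <- max(num / df, .Machine$double.eps)
    x2 <- x2 / delta_bar
  }
  structure(list(statistic = x2, df = df,
                 p_value = stats::pchisq(x2, df, lower.tail = FALSE),
                 delta_bar = delta_bar),
            class = "svy_chisq")
}

#' @export
print.svy_chisq <- function(x, ...) {
  cat(sprintf("Rao-Scott X2 = %.3f, df = %d, p = %.4g (mean deff %.3f)\n",
              x$statistic, x$df, x$p_value, x$delta_bar))
  invisible(x)
}
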