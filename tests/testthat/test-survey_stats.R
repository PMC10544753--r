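degenerate_design <- function(n) {
  survey_design(rep("A", n), paste0("u", seq_len(n)), rep(1, n))
}

test_that("design construction enforces two PSUs per stratum", {
  expect_error(survey_design(c("a", "a", "b", "b"), c("1", "1", "1", "1"),
                             rep(1, 4)), ">= 2 PSUs")
  d <- survey_design(c("a", "a", "b", "b"), c("1", "2", "1", "2"), rep(1, 4))
  expect_identical(d$df, 2L)
  expect_error(survey_design("a", "1", -1), "positive")
})

test_that("PSU labels are nested within stratum, not global", {
  # the same PSU label reused in two strata must count as two PSUs
  d <- survey_design(c("a", "a", "b", "b"), c("1", "2", "1", "2"), rep(1, 4))
  expect_identical(d$df, 4L - 2L)
  est <- weighted_prevalence(c(1, 0, 1, 0), d)
  expect_equal(est$estimate, 0.5)
})

test_that("weighted prevalence reduces to the simple proportion at equal weights", {
  set.seed(43)
  n <- 500
  flags <- runif(n) < 0.3
  d <- degenerate_design(n)
  est <- weighted_prevalence(flags, d)
  expect_equal(est$estimate, mean(flags), tolerance = 1e-15)
  # degenerate all-true case
  est1 <- weighted_prevalence(rep(TRUE, n), d)
  expect_equal(est1$estimate, 1)
  expect_equal(est1$se, 0)
  expect_equal(c(est1$ci_low, est1$ci_high), c(1, 1))
})

test_that("linearized prevalence variance matches a hand-computed toy design", {
  # 2 strata x 2 PSUs, two subjects per PSU, hand-assigned weights
  stratum <- rep(c("s1", "s2"), each = 4)
  psu <- rep(c("p1", "p1", "p2", "p2"), 2)
  w <- c(1, 2, 1, 3, 2, 2, 1, 1)
  y <- c(1, 0, 1, 1, 0, 1, 0, 0)
  d <- survey_design(stratum, psu, w)
  est <- weighted_prevalence(y, d)
  # independent transcription of the estimator and its Taylor variance
  p <- sum(w * y) / sum(w)
  z <- w * (y - p) / sum(w)
  v <- 0
  for (h in c("s1", "s2")) {
    t_hj <- tapply(z[stratum == h], psu[stratum == h], sum)
    v <- v + length(t_hj) / (length(t_hj) - 1) * sum((t_hj - mean(t_hj))^2)
  }
  expect_equal(est$estimate, p, tolerance = 1e-15)
  expect_equal(est$se, sqrt(v), tolerance = 1e-12)
  expect_identical(est$df, 2L)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)
  expect_true(est$ci_low >= 0 && est$ci_high <= 1)
})

test_that("point estimates are invariant to rescaling all weights", {
  sc <- scored_cohort(1200, seed = 47)
  d1 <- cohort_design(sc$cohort)
  d2 <- survey_design(sc$cohort$stratum, sc$cohort$psu, sc$cohort$weight * 57.3)
  flag <- sc$latent == "nash"
  e1 <- weighted_prevalence(flag, d1); e2 <- weighted_prevalence(flag, d2)
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-12)
  expect_equal(e1$se, e2$se, tolerance = 1e-12)
  dat <- cbind(sc$cohort, latent = sc$latent)
  f1 <- fit_weighted_multinomial(latent ~ sex + race_ethnicity, dat, d1)
  f2 <- fit_weighted_multinomial(latent ~ sex + race_ethnicity, dat, d2)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-9)
})

test_that("direct standardization is a standard-weighted mean of group rates", {
  groups <- c(a = 0.02, b = 0.04)
  expect_equal(direct_standardize(groups, c(a = 0.5, b = 0.5)), 0.03)
  # uniform prevalence is invariant under any standard
  expect_equal(direct_standardize(c(a = 0.07, b = 0.07, c = 0.07),
                                  c(a = 0.2, b = 0.5, c = 0.3)), 0.07)
  # a point-mass standard returns that group's prevalence
  expect_equal(direct_standardize(groups, c(a = 1, b = 0)), 0.02)
  expect_error(direct_standardize(groups, c(a = 0.5, z = 0.5)), "same age groups")
  expect_error(direct_standardize(groups, c(a = 0.4, b = 0.4)), "sum to 1")
  # bounds: always between the extreme group prevalences
  set.seed(51)
  for (i in 1:20) {
    gp <- setNames(runif(4), letters[1:4])
    sp <- setNames(as.vector(rmultinom(1, 100, runif(4))) / 100, letters[1:4])
    std <- direct_standardize(gp, sp)
    expect_gte(std, min(gp) - 1e-12)
    expect_lte(std, max(gp) + 1e-12)
  }
})

test_that("bundled standard populations are proper 4-group distributions", {
  for (which in c("us2000", "us1990")) {
    std <- standard_population(which)
    expect_setequal(names(std), c("20_34", "35_49", "50_64", "65_plus"))
    expect_equal(sum(std), 1, tolerance = 1e-12)
    expect_true(all(std > 0))
  }
  # the two standards genuinely differ (the 1990 population is younger)
  expect_gt(standard_population("us1990")[["20_34"]],
            standard_population("us2000")[["20_34"]])
})

test_that("Rao-Scott statistic reduces to classical Pearson at equal weights", {
  set.seed(53)
  n <- 800
  rows <- sample(c("x", "y"), n, TRUE)
  cols <- sample(c("u", "v", "w"), n, TRUE, prob = c(0.5, 0.3, 0.2))
  d <- degenerate_design(n)
  rs <- rao_scott_chi2(rows, cols, d)
  cl <- suppressWarnings(chisq.test(table(rows, cols), correct = FALSE))
  expect_equal(rs$statistic, unname(cl$statistic), tolerance = 1e-9)
  expect_identical(rs$df, 2L)
  expect_equal(rs$delta_bar, 1, tolerance = 1e-9)
  # and the uncorrected flag gives the same weighted Pearson value here
  expect_equal(rao_scott_chi2(rows, cols, d, correction = FALSE)$statistic,
               rs$statistic, tolerance = 1e-9)
})

test_that("Rao-Scott p-value vanishes under perfect association", {
  n <- 400
  rows <- rep(c("x", "y"), each = n / 2)
  cols <- rep(c("u", "v"), each = n / 2)
  rs <- rao_scott_chi2(rows, cols, degenerate_design(n))
  expect_lt(rs$p_value, 1e-10)
})

test_that("null p-values are uniform under an independence model", {
  set.seed(59)
  n <- 10000
  pvals <- replicate(500, {
    rows <- sample(c("x", "y"), n, TRUE)
    cols <- sample(c("u", "v", "w"), n, TRUE, prob = c(0.5, 0.3, 0.2))
    rao_scott_chi2(rows, cols, degenerate_design(n))$p_value
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("weighted multinomial matches ordinary MLE at equal weights", {
  sc <- scored_cohort(2000, seed = 61)
  dat <- cbind(sc$cohort, latent = sc$latent)
  d <- degenerate_design(nrow(dat))
  # binary outcome against glm
  dat$bin <- factor(ifelse(dat$latent == "nash", "nash", "normal_mild"),
                    levels = c("normal_mild", "nash"))
  fit <- fit_weighted_multinomial(bin ~ race_ethnicity + sex + urbanization,
                                  dat, d)
  g <- glm(bin ~ race_ethnicity + sex + urbanization, data = dat,
           family = binomial, control = list(epsilon = 1e-14))
  expect_lt(max(abs(fit$coef[1, ] - coef(g))), 1e-6)
  # three-class outcome against an independent optimizer
  skip_if_not_installed("nnet")
  fit3 <- fit_weighted_multinomial(latent ~ race_ethnicity + sex, dat, d)
  m <- nnet::multinom(latent ~ race_ethnicity + sex, dat, trace = FALSE,
                      reltol = 1e-14, maxit = 1000)
  expect_lt(max(abs(fit3$coef - coef(m))), 1e-4)
})

test_that("rank-deficient covariates fail naming the offending column", {
  sc <- scored_cohort(500, seed = 67)
  dat <- cbind(sc$cohort, latent = sc$latent)
  dat$constant <- "only_level"
  d <- degenerate_design(nrow(dat))
  expect_error(fit_weighted_multinomial(latent ~ sex + constant, dat, d),
               "contrasts|rank deficient")
  dat$dup <- dat$sex
  expect_error(fit_weighted_multinomial(latent ~ sex + dup, dat, d),
               "rank deficient")
})

test_that("rows with missing covariates are listwise-deleted with their design rows", {
  sc <- scored_cohort(1000, seed = 71)
  dat <- cbind(sc$cohort, latent = sc$latent)
  dat$education[1:50] <- NA
  d <- cohort_design(sc$cohort)
  fit <- fit_weighted_multinomial(latent ~ education, dat, d)
  expect_identical(fit$n, nrow(dat) - 50L)
})

test_that("design-based prevalence intervals achieve near-nominal coverage", {
  hits <- 0L
  reps <- 100
  for (i in seq_len(reps)) {
    sim <- generate_cohort(cohort_config(n_subjects = 10000, seed = 5000 + i,
                                         missingness_rate = 0))
    d <- cohort_design(sim$cohort)
    est <- weighted_prevalence(sim$latent == "nash", d)
    if (est$ci_low <= 0.08 && 0.08 <= est$ci_high) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
  expect_lte(hits, 99L)
})
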