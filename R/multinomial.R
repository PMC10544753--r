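#' Survey-weighted multinomial logistic regression
#'
#' Fits a baseline-category multinomial logit by maximizing the weighted
#' pseudo-log-likelihood `sum_i w_i log p_i(y_i)` with full Newton-Raphson
#' iterations (analytic gradient and expected information, step-halving on
#' any decrease). The covariance matrix is the design-based sandwich:
#' bread = inverse information at the solution, meat = Taylor-linearized
#' covariance of the total score over strata and PSUs. With equal weights
#' and an each-subject-its-own-PSU design the point estimates coincide with
#' the ordinary maximum-likelihood fit.
#'
#' The first factor level of the outcome is the reference category (for
#' the three-class liver labels, `normal_mild`), so each non-reference
#' equation contrasts that level against the reference and `exp(coef)` is
#' the corresponding odds ratio.
#'
#' @param formula Model formula, e.g.
#'   `label_hair ~ race_ethnicity + sex + age_group`.
#' @param data data.frame holding the outcome and covariates. Rows with
#'   missing values in any model variable are dropped (listwise deletion)
#'   together with their design rows.
#' @param design A [survey_design()] aligned with `data` rows.
#' @param tol Convergence tolerance on the max-norm of the gradient of the
#'   mean-weight-normalized pseudo-log-likelihood.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `"svy_multinom"` with elements `coef` (matrix,
#'   one row per non-reference outcome level), `vcov`, `se`, `levels`,
#'   `df` (design degrees of freedom), `n`, `iterations`, and
#'   `or_table()`-ready metadata.
#' @seealso [or_table()]
#' @export
fit_weighted_multinomial <- function(formula, data, design,
                                     tol = 1e-8, max_iter = 100L) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  complete <- stats::complete.cases(mf)
  if (!all(complete)) {
    mf <- mf[complete, , drop = FALSE]
    design <- survey_design(design$stratum[complete], design$psu[complete],
                            design$weight[complete])
  }
  y <- factor(stats::model.response(mf))
  y <- droplevels(y)
  K <- nlevels(y)
  if (K < 2) stop("outcome must have at least two observed levels")
  for (v in names(mf)[-1]) {
    x <- mf[[v]]
    if ((is.factor(x) || is.character(x)) &&
        length(unique(as.character(x))) < 2L) {
      stop("covariate has no variation (rank deficient): ", v)
    }
  }
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("model matrix is rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  w <- design$weight / mean(design$weight)  # scale-invariant point estimates
  Y <- matrix(0, n, K - 1)                  # indicators of non-reference levels
  for (k in 2:K) Y[, k - 1] <- as.numeric(y == levels(y)[k])

  beta <- matrix(0, K - 1, p)
  loglik <- function(beta) {
    eta <- X %*% t(beta)
    den <- 1 + rowSums(exp(eta))
    sum(w * (rowSums(Y * eta) - log(den)))
  }
  probs <- function(beta) {
    eta <- X %*% t(beta)
    expeta <- exp(eta)
    expeta / (1 + rowSums(expeta))
  }
  ll <- loglik(beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    P <- probs(beta)                        # n x (K-1)
    resid <- Y - P
    g <- crossprod(X, w * resid)            # p x (K-1); gradient blocks
    gnorm <- max(abs(g))
    if (gnorm < tol) { converged <- TRUE; break }
    # expected information: blocks A[k,l] = X' diag(w (p_k delta_kl - p_k p_l)) X
    H <- matrix(0, (K - 1) * p, (K - 1) * p)
    for (k in seq_len(K - 1)) {
      for (l in seq_len(k)) {
        wt <- if (k == l) w * P[, k] * (1 - P[, k]) else -w * P[, k] * P[, l]
        blk <- crossprod(X, X * wt)
        ri <- (k - 1) * p + seq_len(p); ci <- (l - 1) * p + seq_len(p)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
    }
    step <- solve(H, as.vector(g))          # g stacked by outcome level
    step <- matrix(step, K - 1, p, byrow = TRUE)
    # step-halving if the pseudo-likelihood does not improve
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      llc <- loglik(cand)
      if (llc >= ll - 1e-10 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- cand; ll <- llc
  }
  if (!converged) {
    stop(sprintf("Newton iterations did not converge in %d iterations (gradient norm %.3g)",
                 max_iter, gnorm))
  }
  if (max(abs(beta)) > 15) {
    warning("possible separation: |coefficient| > 15")
  }

  # sandwich: bread = information^{-1}; meat = design covariance of the
  # total score with the original (unscaled) weights' relative values
  P <- probs(beta)
  scores <- matrix(0, n, (K - 1) * p)       # per-unit score contributions
  for (k in seq_len(K - 1)) {
    scores[, (k - 1) * p + seq_len(p)] <- w * (Y[, k] - P[, k]) * X
  }
  H <- matrix(0, (K - 1) * p, (K - 1) * p)
  for (k in seq_len(K - 1)) {
    for (l in seq_len(k)) {
      wt <- if (k == l) w * P[, k] * (1 - P[, k]) else -w * P[, k] * P[, l]
      blk <- crossprod(X, X * wt)
      ri <- (k - 1) * p + seq_len(p); ci <- (l - 1) * p + seq_len(p)
      H[ri, ci] <- blk
      H[ci, ri] <- t(blk)
    }
  }
  meat <- linearized_total_vcov(scores, design)
  bread <- solve(H)
  V <- bread %*% meat %*% bread
  coef_names <- colnames(X)
  dimnames(beta) <- list(levels(y)[-1], coef_names)
  vn <- as.vector(t(outer(levels(y)[-1], coef_names, paste, sep = ":")))
  dimnames(V) <- list(vn, vn)
  se <- matrix(sqrt(diag(V)), K - 1, p, byrow = TRUE,
               dimnames = dimnames(beta))
  structure(list(coef = beta, vcov = V, se = se, levels = levels(y),
                 df = design$df, n = n, iterations = iter,
                 formula = formula, converged = converged),
            class = "svy_multinom")
}

#' @export
print.svy_multinom <- function(x, ...) {
  cat(sprintf("survey-weighted multinomial fit: n = %d, outcome levels: %s\n",
              x$n, paste(x$levels, collapse = ", ")))
  cat(sprintf("(reference level %s; %d Newton iterations; design df %d)\n",
              x$levels[1], x$iterations, x$df))
  print(round(x$coef, 4))
  invisible(x)
}

#' Odds-ratio table from a weighted multinomial fit
#'
#' Exponentiates the coefficients and forms 95 percent confidence intervals
#' with a t quantile on the design degrees of freedom, one row per
#' covariate contrast per non-reference outcome level.
#'
#' @param fit A [fit_weighted_multinomial()] result.
#' @param level Confidence level.
#' @return data.frame with `outcome`, `term`, `or`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
or_table <- function(fit, level = 0.95) {
  tq <- stats::qt(1 - (1 - level) / 2, fit$df)
  rows <- list()
  for (k in rownames(fit$coef)) {
    for (j in colnames(fit$coef)) {
      if (j == "(Intercept)") next
      b <- fit$coef[k, j]; s <- fit$se[k, j]
      tstat <- b / s
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = k, term = j, or = exp(b),
        ci_low = exp(b - tq * s), ci_high = exp(b + tq * s),
        p_value = 2 * stats::pt(-abs(tstat), fit$df),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Unadjusted and adjusted odds ratios for a set of covariates
#'
#' Mirrors the usual risk-factor table: the adjusted odds ratios (AOR) come
#' from the joint model with every covariate; the unadjusted odds ratios
#' (OR) from refitting with each single covariate alone.
#'
#' @param outcome Name of the 3-class outcome column in `data`.
#' @param covariates Character vector of covariate column names.
#' @param data data.frame.
#' @param design A [survey_design()] aligned with `data`.
#' @return data.frame: one row per contrast per non-reference outcome level
#'   with both `or`/`or_ci_low`/`or_ci_high` and `aor`/`aor_ci_low`/
#'   `aor_ci_high` plus the adjusted-model p-value.
#' @export
or_aor_table <- function(outcome, covariates, data, design) {
  f_adj <- stats::reformulate(covariates, response = outcome)
  adj <- or_table(fit_weighted_multinomial(f_adj, data, design))
  names(adj)[names(adj) == "or"] <- "aor"
  names(adj)[names(adj) == "ci_low"] <- "aor_ci_low"
  names(adj)[names(adj) == "ci_high"] <- "aor_ci_high"
  unadj <- do.call(rbind, lapply(covariates, function(v) {
    or_table(fit_weighted_multinomial(
      stats::reformulate(v, response = outcome), data, design))
  }))
  names(unadj)[names(unadj) == "ci_low"] <- "or_ci_low"
  names(unadj)[names(unadj) == "ci_high"] <- "or_ci_high"
  unadj$p_value <- NULL
  merge(unadj, adj, by = c("outcome", "term"), sort = FALSE)
}
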