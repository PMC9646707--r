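# Conventional statistics: univariable screening, group comparisons, and
# multivariable logistic/linear models with goodness-of-fit, discrimination,
# and collinearity diagnostics.

#' Point-biserial correlation
#'
#' The Pearson correlation between a continuous variable and a 0/1 class
#' indicator. Pairs with missing values are dropped.
#'
#' @param x Continuous vector.
#' @param y Binary 0/1 vector of the same length.
#' @return Correlation in `[-1, 1]`.
#' @export
point_biserial <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(y)) < 2) stop("y must contain both classes")
  if (stats::sd(x) == 0) stop("x is constant; correlation undefined")
  stats::cor(x, as.numeric(y))
}

#' Concordance statistic (rank-based AUC)
#'
#' Fraction of positive-negative pairs in which the positive subject has the
#' higher score, ties counted one half; computed via the Mann-Whitney rank
#' statistic with midranks.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Continuous scores.
#' @return Value in `[0, 1]`.
#' @export
c_statistic <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`. `k` counts every estimated
#' parameter including the intercept (and, for Gaussian linear models, the
#' residual variance). Returns `Inf` with a warning when `n <= k + 1`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) {
    warning("AICc undefined for n <= k + 1; returning Inf")
    return(Inf)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Univariable group comparisons between outcome classes
#'
#' For every predictor, compares the two outcome groups with the test the
#' variable's schema declares appropriate: normal-like continuous variables
#' by the unpaired (pooled-variance) t-test, skewed continuous variables by
#' the Mann-Whitney U test, and categorical (binary/ordinal) variables by the
#' chi-square test, replaced by Fisher's exact test whenever any expected
#' cell count falls below 5 or the table holds fewer than 40 observations.
#' Originally missing values are excluded per-variable.
#'
#' @param cohort An `srg_cohort` with both outcome classes present.
#' @return A data frame `(variable, test, statistic, p_value)`.
#' @export
group_compare <- function(cohort) {
  y <- cohort$gh_label
  if (length(unique(y)) < 2) stop("both outcome groups must be nonempty")
  obs <- cohort_observed(cohort)
  pred_schema <- cohort$schema[cohort$schema$role != "target", , drop = FALSE]
  rows <- lapply(seq_len(ncol(obs)), function(j) {
    v <- obs[[j]]
    ok <- !is.na(v)
    vj <- v[ok]; yj <- y[ok]
    kind <- pred_schema$kind[j]
    res <- tryCatch({
      if (kind %in% c("continuous", "percentage")) {
        if (isTRUE(pred_schema$skewed[j])) {
          ht <- stats::wilcox.test(vj ~ yj, exact = FALSE)
          c("Mann-Whitney U", unname(ht$statistic), ht$p.value)
        } else {
          ht <- stats::t.test(vj ~ yj, var.equal = TRUE)
          c("unpaired t", unname(ht$statistic), ht$p.value)
        }
      } else {
        tab <- table(factor(vj), factor(yj))
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        # Cochran-style validity rule: exact test for small tables or sparse
        # expected counts
        if (sum(tab) < 40 || any(expected < 5)) {
          ht <- stats::fisher.test(tab)
          c("Fisher exact", NA_real_, ht$p.value)
        } else {
          ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
          c("chi-square", unname(ht$statistic), ht$p.value)
        }
      }
    }, error = function(e) c("failed", NA_real_, NA_real_))
    data.frame(variable = pred_schema$name[j], test = res[1],
               statistic = as.numeric(res[2]), p_value = as.numeric(res[3]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column j on
#' the remaining columns. Exactly collinear columns are flagged with an
#' infinite VIF and a warning.
#'
#' @param design Numeric matrix or data frame with at least two columns.
#' @return Named numeric vector of VIFs (each >= 1).
#' @export
compute_vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2) stop("VIF needs at least two columns")
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    # exact collinearity makes this auxiliary fit "perfect"; we flag it below
    r2j <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2j > 1 - 1e-12) Inf else 1 / (1 - r2j)
  }, numeric(1))
  names(vifs) <- colnames(X)
  if (any(!is.finite(vifs))) {
    warning("exactly collinear column(s): ",
            paste(names(vifs)[!is.finite(vifs)], collapse = ", "))
  }
  vifs
}

#' Multivariable logistic regression with small-sample diagnostics
#'
#' Maximum-likelihood logistic fit of the hypertrophy label on the given
#' terms, with Wald 95% confidence intervals on the odds-ratio scale,
#' McFadden's pseudo-R-squared (`1 - lnL_model / lnL_null`), AICc with
#' `k = terms + 1`, and the concordance statistic of the fitted
#' probabilities. Warns when the events-per-variable rule (at least five
#' positive outcomes per included term) is violated, and flags
#' non-convergence or likely complete separation instead of returning silent
#' estimates.
#'
#' @param cohort An imputed `srg_cohort` (imputation is applied on the fly if
#'   needed).
#' @param terms Character vector of predictor names (may be empty for the
#'   intercept-only model).
#' @return An object of class `srg_logit`.
#' @export
fit_logistic <- function(cohort, terms) {
  X <- as.data.frame(cohort_matrix(cohort))
  y <- cohort$gh_label
  npos <- sum(y)
  if (length(terms) > 0 && npos < 5 * length(terms)) {
    warning("events-per-variable rule violated: ", npos, " positives for ",
            length(terms), " terms (at least ", 5 * length(terms), " advised)")
  }
  dat <- cbind(data.frame(.y = y), X[, terms, drop = FALSE])
  fit <- stats::glm(.y ~ ., family = stats::binomial(), data = dat)
  null_fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = dat)
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  sm <- summary(fit)$coefficients
  converged <- fit$converged && all(abs(sm[, "Estimate"]) < 25) &&
    all(sm[, "Std. Error"] < 1e3)
  if (!converged) {
    warning("logistic fit did not converge cleanly (possible complete separation)")
  }
  coefs <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  k <- length(terms) + 1
  n <- length(y)
  out <- list(
    terms = terms,
    coefficients = coefs,
    se = se,
    odds_ratio = exp(coefs),
    or_ci_low = exp(coefs - stats::qnorm(0.975) * se),
    or_ci_high = exp(coefs + stats::qnorm(0.975) * se),
    p_value = sm[, "Pr(>|z|)"],
    lnl_model = ll, lnl_null = ll0,
    pseudo_r2 = if (abs(ll0) < 1e-12) 0 else 1 - ll / ll0,
    aicc = aicc(ll, k, n),
    c_statistic = if (length(terms)) c_statistic(y, stats::fitted(fit)) else 0.5,
    converged = converged, n = n, n_positive = npos, fit = fit)
  class(out) <- "srg_logit"
  out
}

#' @export
print.srg_logit <- function(x, ...) {
  cat(sprintf("Multivariable logistic model (%d subjects, %d positives)\n",
              x$n, x$n_positive))
  cat(sprintf("  pseudo-R2 = %.2f, AICc = %.1f, C-statistic = %.2f%s\n",
              x$pseudo_r2, x$aicc, x$c_statistic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$terms)) {
    tab <- data.frame(OR = x$odds_ratio, `2.5%` = x$or_ci_low,
                      `97.5%` = x$or_ci_high, p = x$p_value,
                      check.names = FALSE)[-1, , drop = FALSE]
    print(round(tab, 4))
  }
  invisible(x)
}

#' Multivariable linear regression with standardized coefficients and VIFs
#'
#' Ordinary least squares of the continuous target (MaxGD, micrometres) on
#' the given terms. Reported are the raw-scale R-squared, AICc with
#' `k = terms + 2` (intercept plus residual variance), per-term standardized
#' beta (`b * sd(x) / sd(y)`), t-ratios, p-values, and VIFs, plus the
#' model-level VIF threshold `1 / (1 - R^2)` used as a secondary
#' multicollinearity rule.
#'
#' @param cohort An `srg_cohort`.
#' @param terms Character vector of predictor names (at least one).
#' @return An object of class `srg_linfit`.
#' @export
fit_linear <- function(cohort, terms) {
  stopifnot(length(terms) >= 1)
  X <- as.data.frame(cohort_matrix(cohort))
  y <- cohort$maxgd
  n <- length(y)
  if (n <= length(terms) + 2) stop("too few subjects for ", length(terms), " terms")
  dat <- cbind(data.frame(.y = y), X[, terms, drop = FALSE])
  qrX <- qr(as.matrix(cbind(1, X[, terms, drop = FALSE])))
  if (qrX$rank < length(terms) + 1) {
    dep <- terms[qrX$pivot[seq.int(qrX$rank + 1, length(terms) + 1)] - 1]
    stop("rank-deficient design; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  coefs <- sm$coefficients
  sds <- vapply(X[, terms, drop = FALSE], stats::sd, numeric(1))
  std_beta <- coefs[-1, "Estimate"] * sds / stats::sd(y)
  vifs <- if (length(terms) >= 2) {
    compute_vif(X[, terms, drop = FALSE])
  } else {
    stats::setNames(1, terms)
  }
  r2 <- sm$r.squared
  k <- length(terms) + 2
  out <- list(
    terms = terms,
    coefficients = coefs[, "Estimate"],
    std_beta = std_beta,
    t_ratio = coefs[-1, "t value"],
    p_value = coefs[-1, "Pr(>|t|)"],
    vif = vifs,
    r2 = r2,
    aicc = aicc(as.numeric(stats::logLik(fit)), k, n),
    vif_threshold = 1 / (1 - r2),
    n = n, fit = fit)
  class(out) <- "srg_linfit"
  out
}

#' @export
print.srg_linfit <- function(x, ...) {
  cat(sprintf("Multivariable linear model (%d subjects)\n", x$n))
  cat(sprintf("  R2 = %.2f, AICc = %.1f, model VIF threshold = %.2f\n",
              x$r2, x$aicc, x$vif_threshold))
  tab <- data.frame(beta = x$std_beta, VIF = x$vif, t = x$t_ratio,
                    p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

#' Rank predictors by absolute point-biserial correlation
#'
#' Screens every predictor against the binary outcome with the
#' point-biserial correlation and ranks them by absolute value, the
#' correlation-based competitor to the ML score ranking.
#'
#' @param cohort An `srg_cohort`.
#' @return A data frame `(variable, r, abs_r, rank)` ordered by descending
#'   `abs_r`.
#' @export
correlation_ranking <- function(cohort) {
  X <- as.data.frame(cohort_matrix(cohort))
  y <- cohort$gh_label
  r <- vapply(X, function(v) {
    if (stats::sd(v) == 0) return(0)
    point_biserial(v, y)
  }, numeric(1))
  out <- data.frame(variable = names(r), r = as.numeric(r),
                    abs_r = abs(as.numeric(r)), stringsAsFactors = FALSE)
  out$rank <- rank_desc(out$abs_r)
  out <- out[order(-out$abs_r, out$variable), ]
  rownames(out) <- NULL
  out
}
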