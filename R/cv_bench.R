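# LOO-CV driver for the symbolic-regression classifier, classification
# metrics, permutation test, baseline learner bench, and the seven-measure
# variable-importance suite.

#' Classification metrics from scores
#'
#' AUC by the Mann-Whitney rank statistic with ties counted one half;
#' accuracy, precision, recall, and F1 from the confusion matrix after
#' thresholding the scores. Precision is 0 when nothing is predicted
#' positive, and F1 is 0 when its denominator vanishes.
#'
#' @param labels Binary 0/1 vector containing both classes.
#' @param scores Continuous prediction scores.
#' @param threshold Classification threshold on the score (default 0.5).
#' @return A list `(auc, accuracy, precision, recall, f1)`, class
#'   `srg_metrics`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(auc = c_statistic(labels, scores),
                 accuracy = (tp + tn) / length(labels),
                 precision = precision, recall = recall, f1 = f1),
            class = "srg_metrics")
}

#' @export
print.srg_metrics <- function(x, ...) {
  cat(sprintf("AUC %.3f | accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f\n",
              x$auc, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Leave-one-out cross-validated symbolic regression
#'
#' For each trial, every subject is held out in turn; on the remaining
#' subjects, `species` independent evolutionary runs (distinct derived seeds)
#' are evolved and merged, and the held-out subject is scored by the
#' trimmed-mean ensemble of the fold's Pareto front. Pooled metrics are
#' computed over the n held-out scores. Across `trials` consecutive LOO-CV
#' repetitions, the one with the highest pooled AUC is returned together with
#' its merged model archive (all folds and species, provenance recorded).
#'
#' @param cohort An `srg_cohort` (imputed on the fly if needed).
#' @param config A [gp_config()]; its seed is the master seed for all runs.
#' @param species Independent evolution runs per fold (>= 1).
#' @param trials Number of consecutive LOO-CV trials (>= 1).
#' @param trim_fraction Trimmed-mean fraction for the fold ensembles.
#' @return An `srg_cvrun`: held-out `scores`, pooled `metrics`, merged
#'   `archive`, the winning `trial` index, and `trial_aucs`.
#' @export
loo_cv_srgp <- function(cohort, config = gp_config(), species = 4, trials = 10,
                        trim_fraction = 0.1) {
  stopifnot(species >= 1, trials >= 1)
  X <- as.data.frame(cohort_matrix(cohort))
  y <- cohort$gh_label
  n <- nrow(X)
  if (length(unique(y)) < 2) stop("AUC pooling requires both classes in the cohort")
  best <- NULL
  trial_aucs <- numeric(trials)
  for (t in seq_len(trials)) {
    scores <- numeric(n)
    fold_archives <- vector("list", n * species)
    for (i in seq_len(n)) {
      ytr <- y[-i]
      if (length(unique(ytr)) < 2) {
        stop("training fold ", i, " contains a single class; flagging fold")
      }
      runs <- lapply(seq_len(species), function(s) {
        cfg <- config
        cfg$seed <- derive_seed(config$seed, t, i, s)
        evolve(X[-i, , drop = FALSE], ytr, cfg,
               provenance = c(trial = t, fold = i, species = s))
      })
      fold_archives[(i - 1) * species + seq_len(species)] <- runs
      front <- pareto_front(merge_archives(runs))
      scores[i] <- ensemble_predict(front, X[i, , drop = FALSE], trim_fraction)
    }
    metrics <- classification_metrics(y, scores)
    trial_aucs[t] <- metrics$auc
    if (is.null(best) || metrics$auc > best$metrics$auc) {
      best <- list(scores = scores, metrics = metrics,
                   archive = merge_archives(fold_archives), trial = t)
    }
  }
  best$trial_aucs <- trial_aucs
  class(best) <- "srg_cvrun"
  best
}

#' @export
print.srg_cvrun <- function(x, ...) {
  cat(sprintf("LOO-CV symbolic regression: best of %d trial(s) (trial %d)\n",
              length(x$trial_aucs), x$trial))
  print(x$metrics)
  print(x$archive)
  invisible(x)
}

# --- cross-validated accuracy scorer used by the permutation test ----------

# deterministic stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  set.seed(derive_seed(seed, 77))
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# built-in classifiers: fit on (xtr, ytr), return scores in [0, 1] for xte
classifier_fun <- function(classifier, seed) {
  if (is.function(classifier)) return(classifier)
  switch(classifier,
    centroid = function(xtr, ytr, xte) {
      mu <- colMeans(xtr)
      sdv <- pmax(apply(xtr, 2, stats::sd), 1e-9)
      ztr <- scale(xtr, mu, sdv)
      zte <- scale(xte, mu, sdv)
      c1 <- colMeans(ztr[ytr == 1, , drop = FALSE])
      c0 <- colMeans(ztr[ytr == 0, , drop = FALSE])
      d1 <- rowSums(sweep(zte, 2, c1)^2)
      d0 <- rowSums(sweep(zte, 2, c0)^2)
      stats::plogis(d0 - d1)
    },
    rf = function(xtr, ytr, xte) {
      set.seed(derive_seed(seed, 88))
      fit <- randomForest::randomForest(xtr, factor(ytr, levels = c(0, 1)),
                                        ntree = 200)
      stats::predict(fit, xte, type = "prob")[, "1"]
    },
    stop("unknown classifier: ", classifier))
}

cv_accuracy <- function(X, y, fold_id, clf) {
  pred <- numeric(length(y))
  for (f in unique(fold_id)) {
    te <- fold_id == f
    pred[te] <- clf(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE])
  }
  mean(as.integer(pred >= 0.5) == y)
}

#' Permutation test for classifier significance
#'
#' Scores the cohort with a cross-validated classifier, then repeats the
#' identical procedure on `B` uniformly permuted label vectors (the CV
#' partition is held fixed). The empirical p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, so it is never zero.
#'
#' @param cohort An `srg_cohort`.
#' @param classifier `"rf"` (random forest, the default), `"centroid"`
#'   (nearest shrunken-free class centroid; fast, useful for simulation), or
#'   a function `(xtr, ytr, xte) -> scores`.
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed for folds and permutations.
#' @param folds Stratified CV folds for the accuracy scorer.
#' @return An `srg_permtest`: `observed_score`, `null_scores`, `p_value`,
#'   `B`.
#' @export
permutation_test <- function(cohort, classifier = "rf", B = 5000, seed = 1,
                             folds = 5) {
  stopifnot(B >= 1)
  X <- cohort_matrix(cohort)
  y <- cohort$gh_label
  fold_id <- stratified_folds(y, folds, seed)
  clf <- classifier_fun(classifier, seed)
  observed <- cv_accuracy(X, y, fold_id, clf)
  perms <- permute_labels(y, B, derive_seed(seed, 5))
  null_scores <- vapply(perms, function(yp) cv_accuracy(X, yp, fold_id, clf),
                        numeric(1))
  structure(list(observed_score = observed, null_scores = null_scores,
                 p_value = (1 + sum(null_scores >= observed)) / (B + 1),
                 B = B,
                 classifier = if (is.function(classifier)) "custom" else classifier),
            class = "srg_permtest")
}

#' @export
print.srg_permtest <- function(x, ...) {
  cat(sprintf("Permutation test (%s classifier, B = %d)\n", x$classifier, x$B))
  cat(sprintf("  observed CV accuracy %.3f, null mean %.3f, p = %.4g\n",
              x$observed_score, mean(x$null_scores), x$p_value))
  invisible(x)
}

# --- nine-learner benchmark -----------------------------------------------

bench_learners <- function() {
  c("Linear Regression", "Lasso Regression", "Ridge Regression",
    "Logistic Regression", "Naive Bayes", "SVM", "Random Forest",
    "XGBoost", "Symbolic Regression via GP")
}

# each learner maps (xtr, ytr, xte, seed) -> continuous scores for xte
learner_fun <- function(name, gp_cfg, trim_fraction) {
  switch(name,
    "Linear Regression" = function(xtr, ytr, xte, seed) {
      df <- as.data.frame(xtr); df$.y <- ytr
      fit <- stats::lm(.y ~ ., data = df)
      # p > n leaves the fit rank-deficient by design; aliased terms drop out
      unname(suppressWarnings(stats::predict(fit, as.data.frame(xte))))
    },
    "Lasso Regression" = ,
    "Ridge Regression" = function(xtr, ytr, xte, seed) {
      alpha <- if (name == "Lasso Regression") 1 else 0
      set.seed(seed)
      cvfit <- glmnet::cv.glmnet(as.matrix(xtr), ytr, alpha = alpha,
                                 nfolds = 5, family = "gaussian")
      as.numeric(stats::predict(cvfit, as.matrix(xte), s = "lambda.min"))
    },
    "Logistic Regression" = function(xtr, ytr, xte, seed) {
      # ridge-penalized: p > n makes the unpenalized MLE ill-posed; small
      # internal CV folds routinely trigger glmnet's class-size caution
      set.seed(seed)
      cvfit <- suppressWarnings(
        glmnet::cv.glmnet(as.matrix(xtr), ytr, alpha = 0, nfolds = 5,
                          family = "binomial"))
      as.numeric(stats::predict(cvfit, as.matrix(xte), s = "lambda.min",
                                type = "response"))
    },
    "Naive Bayes" = function(xtr, ytr, xte, seed) {
      fit <- e1071::naiveBayes(as.data.frame(xtr), factor(ytr, levels = c(0, 1)))
      stats::predict(fit, as.data.frame(xte), type = "raw")[, "1"]
    },
    "SVM" = function(xtr, ytr, xte, seed) {
      set.seed(seed)
      fit <- e1071::svm(xtr, factor(ytr, levels = c(0, 1)), probability = TRUE)
      attr(stats::predict(fit, xte, probability = TRUE), "probabilities")[, "1"]
    },
    "Random Forest" = function(xtr, ytr, xte, seed) {
      set.seed(seed)
      fit <- randomForest::randomForest(xtr, factor(ytr, levels = c(0, 1)),
                                        ntree = 300)
      stats::predict(fit, xte, type = "prob")[, "1"]
    },
    "XGBoost" = function(xtr, ytr, xte, seed) {
      set.seed(seed)
      fit <- fit_xgb(as.matrix(xtr), ytr)
      stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(xte)))
    },
    "Symbolic Regression via GP" = function(xtr, ytr, xte, seed) {
      cfg <- gp_cfg
      cfg$seed <- seed
      arch <- evolve(xtr, ytr, cfg)
      ensemble_predict(pareto_front(arch), xte, trim_fraction)
    },
    stop("unknown learner: ", name))
}

#' Benchmark nine classifiers under a common LOO-CV split
#'
#' Evaluates simple linear regression, Lasso, Ridge, (ridge-penalized)
#' logistic regression, naive Bayes, an RBF support vector machine, random
#' forest, XGBoost, and symbolic regression via genetic programming on the
#' same leave-one-out split. Regression learners score the 0/1 label
#' directly; every score vector is thresholded at 0.5 for the confusion
#' metrics and used as-is for AUC. A learner that fails on a fold yields a
#' missing metrics row with a warning.
#'
#' @param cohort An `srg_cohort`.
#' @param seed Master seed for the stochastic learners.
#' @param gp_config GP settings for the symbolic-regression rows; sized down
#'   by default so the 43-fold LOO stays tractable.
#' @param trim_fraction Ensemble trim for the GP learner.
#' @param learners Subset of learner names (default all nine).
#' @return A data frame with one row per learner and columns
#'   `(model, auc, accuracy, precision, recall, f1)`.
#' @export
baseline_bench <- function(cohort, seed = 1,
                           gp_config = srgprank::gp_config(population_size = 100,
                                                           generations = 20),
                           trim_fraction = 0.1,
                           learners = bench_learners()) {
  X <- cohort_matrix(cohort)
  y <- cohort$gh_label
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X)
  rows <- lapply(learners, function(nm) {
    fn <- learner_fun(nm, gp_config, trim_fraction)
    scores <- rep(NA_real_, n)
    ok <- TRUE
    for (i in seq_len(n)) {
      res <- tryCatch(
        fn(X[-i, , drop = FALSE], y[-i], X[i, , drop = FALSE],
           derive_seed(seed, match(nm, bench_learners()), i)),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning("learner '", nm, "' failed on fold ", i, ": ",
                conditionMessage(res))
        ok <- FALSE
        break
      }
      scores[i] <- res
    }
    if (!ok) {
      return(data.frame(model = nm, auc = NA_real_, accuracy = NA_real_,
                        precision = NA_real_, recall = NA_real_, f1 = NA_real_))
    }
    m <- classification_metrics(y, scores)
    data.frame(model = nm, auc = m$auc, accuracy = m$accuracy,
               precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- seven-measure importance suite ---------------------------------------

# gradient-boosted classifier with fixed conventional settings
fit_xgb <- function(X, y, nrounds = 50) {
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   max_depth = 3, eta = 0.3, nthread = 1),
                     data = dm, nrounds = nrounds, verbose = 0)
}

# one-way ANOVA F statistic of x across the two outcome groups
f_statistic <- function(x, y) {
  groups <- split(x, y)
  k <- length(groups)
  n <- length(x)
  gm <- mean(x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw <= 0 || n - k <= 0) return(0)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Approximate maximal information coefficient
#'
#' Grid-search approximation of MIC: over all grid shapes `(i, j)` with
#' `i * j <= n^0.6`, the variables are discretized into equal-frequency bins
#' and the normalized mutual information `I / log(min(i, j))` is maximized.
#' Equal-frequency binning approximates the exact partition optimization of
#' the reference algorithm; adequate for ranking, not for exact MIC values.
#'
#' @param x,y Numeric vectors.
#' @return Approximate MIC in `[0, 1]`.
#' @export
mic_score <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  bmax <- max(4, floor(n^0.6))
  bin <- function(v, nb) {
    u <- unique(v)
    if (length(u) <= nb) return(factor(v))  # discrete: one bin per value
    cuts <- unique(stats::quantile(v, probs = seq(0, 1, length.out = nb + 1)))
    if (length(cuts) < 3) return(factor(v > cuts[1]))
    cut(v, cuts, include.lowest = TRUE)
  }
  best <- 0
  for (i in 2:min(bmax %/% 2, 16)) {
    for (j in 2:min(bmax %/% i, 16)) {
      bx <- bin(x, i); by <- bin(y, j)
      if (is.null(bx) || is.null(by)) next
      tab <- table(bx, by) / n
      px <- rowSums(tab); py <- colSums(tab)
      nz <- tab > 0
      mi <- sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
      norm <- mi / log(min(nlevels(bx), nlevels(by)))
      if (is.finite(norm) && norm > best) best <- norm
    }
  }
  best
}

#' Seven-measure variable-importance suite
#'
#' Computes seven variable-importance measures on the same cohort: the
#' archive-based ML score from symbolic regression, the one-way ANOVA
#' F-statistic, the (approximate) maximal information coefficient, impurity
#' reduction and permutation importance from a random forest, and split
#' count and coverage from XGBoost. Each measure is rescaled to sum 100
#' (negative permutation importances floored at zero; a constant predictor
#' scores 0), and the eighth column is their arithmetic mean, which also
#' sums to 100.
#'
#' @param cohort An `srg_cohort`.
#' @param ml_score Named ML-score vector over all predictors, e.g. the
#'   `ml_score` column of [importance_table()].
#' @param seed Seed for the forest and boosting fits.
#' @return A data frame, one row per predictor, columns `ml_gp`, `f_stat`,
#'   `mic`, `rf_impurity`, `xgb_split`, `xgb_cover`, `rf_permutation`,
#'   `average`; every column sums to 100.
#' @export
importance_suite <- function(cohort, ml_score, seed = 1) {
  X <- cohort_matrix(cohort)
  y <- cohort$gh_label
  vars <- colnames(X)
  stopifnot(all(vars %in% names(ml_score)))

  fstat <- vapply(vars, function(v) f_statistic(X[, v], y), numeric(1))
  mic <- vapply(vars, function(v) mic_score(X[, v], y), numeric(1))

  set.seed(derive_seed(seed, 1))
  rf <- randomForest::randomForest(X, factor(y, levels = c(0, 1)), ntree = 500,
                                   importance = TRUE)
  rf_imp <- randomForest::importance(rf)
  rf_gini <- rf_imp[vars, "MeanDecreaseGini"]
  rf_perm <- rf_imp[vars, "MeanDecreaseAccuracy"]

  set.seed(derive_seed(seed, 2))
  xgb <- fit_xgb(X, y)
  xim <- xgboost::xgb.importance(feature_names = vars, model = xgb)
  xsplit <- stats::setNames(numeric(length(vars)), vars)
  xcover <- xsplit
  xsplit[xim$Feature] <- xim$Frequency
  xcover[xim$Feature] <- xim$Cover

  out <- data.frame(
    variable = vars,
    ml_gp = normalize_to_100(ml_score[vars]),
    f_stat = normalize_to_100(fstat),
    mic = normalize_to_100(mic),
    rf_impurity = normalize_to_100(rf_gini),
    xgb_split = normalize_to_100(xsplit),
    xgb_cover = normalize_to_100(xcover),
    rf_permutation = normalize_to_100(rf_perm),
    stringsAsFactors = FALSE)
  out$average <- rowMeans(out[, c("ml_gp", "f_stat", "mic", "rf_impurity",
                                  "xgb_split", "xgb_cover", "rf_permutation")])
  rownames(out) <- NULL
  out
}
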