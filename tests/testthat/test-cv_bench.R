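test_that("classification metrics follow the confusion-matrix definitions", {
  y <- rep(c(1, 0), c(4, 4))
  perfect <- c(0.9, 0.8, 0.9, 0.7, 0.1, 0.2, 0.3, 0.4)
  m <- classification_metrics(y, perfect)
  expect_equal(unlist(unclass(m)), c(auc = 1, accuracy = 1, precision = 1,
                                     recall = 1, f1 = 1))
  # confusion matrix TP=8 FP=3 FN=7 TN=25 on 43 subjects
  y43 <- rep(c(1, 1, 0, 0), c(8, 7, 3, 25))
  s43 <- rep(c(0.9, 0.1, 0.9, 0.1), c(8, 7, 3, 25))
  m43 <- classification_metrics(y43, s43)
  expect_equal(m43$accuracy, 33 / 43)
  expect_equal(m43$precision, 8 / 11)
  expect_equal(m43$recall, 8 / 15)
  expect_equal(m43$f1, 2 * (8 / 11) * (8 / 15) / (8 / 11 + 8 / 15))
  # all-negative predictions with positives present
  m0 <- classification_metrics(c(1, 1, 0), c(0.1, 0.2, 0.3))
  expect_equal(c(m0$precision, m0$recall, m0$f1), c(0, 0, 0))
})

test_that("the F1 identity and accuracy identity hold on random score vectors", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- runif(n)
    m <- classification_metrics(y, s)
    denom <- m$precision + m$recall
    expect_equal(m$f1,
                 if (denom > 0) 2 * m$precision * m$recall / denom else 0)
    pred <- as.integer(s >= 0.5)
    expect_equal(m$accuracy, mean(pred == y))
  }
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  for (i in 1:10) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(40), 2)  # induce ties
    expect_equal(c_statistic(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("LOO-CV scores every subject once and returns the best trial", {
  co <- tiny_cohort(seed = 8, n = 14, p = 4)
  cfg <- gp_config(population_size = 24, generations = 4, seed = 17)
  cv <- loo_cv_srgp(co, cfg, species = 2, trials = 2)
  expect_length(cv$scores, 14)
  expect_true(all(is.finite(cv$scores)))
  expect_length(cv$trial_aucs, 2)
  expect_equal(cv$trial, which.max(cv$trial_aucs))
  expect_equal(cv$metrics$auc, max(cv$trial_aucs))
  # merged archive holds species * folds final populations of the best trial
  expect_equal(cv$archive$totals, 14 * 2 * 24)
  prov <- vapply(cv$archive$models, function(m) {
    paste(m$provenance$fold, m$provenance$species, m$provenance$index)
  }, character(1))
  expect_false(anyDuplicated(prov) > 0)
  cv2 <- loo_cv_srgp(co, cfg, species = 2, trials = 2)
  expect_identical(cv$scores, cv2$scores)
})

test_that("the permutation p-value follows the add-one rule and is never zero", {
  co <- tiny_cohort(seed = 10, n = 30, p = 5)
  pt <- permutation_test(co, classifier = "centroid", B = 39, seed = 4)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_scores >= pt$observed_score)) / (39 + 1))
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  expect_length(pt$null_scores, 39)
  pt2 <- permutation_test(co, classifier = "centroid", B = 39, seed = 4)
  expect_identical(pt$null_scores, pt2$null_scores)
  # strongly separated data: observed beats every permutation
  spec <- synthetic_spec(n = 40, p = 4,
                         signal_vars = list(list(index = 1, kind = "linear",
                                                 effect = 4)),
                         collinear_pairs = list(), missing_rate = 0,
                         noise_sd = 0.2, seed = 2)
  co2 <- generate_cohort(spec)$cohort
  pt3 <- permutation_test(co2, classifier = "centroid", B = 99, seed = 5)
  expect_equal(pt3$p_value, 1 / 100)
})

test_that("the nine-learner bench evaluates every model under one LOO split", {
  co <- tiny_cohort(seed = 12, n = 16, p = 6)
  bench <- baseline_bench(co, seed = 3,
                          gp_config = gp_config(population_size = 20,
                                                generations = 3))
  expect_equal(nrow(bench), 9)
  expect_setequal(bench$model, srgprank:::bench_learners())
  metrics <- as.matrix(bench[, c("auc", "accuracy", "precision", "recall", "f1")])
  expect_true(all(metrics >= 0 & metrics <= 1, na.rm = TRUE))
  again <- baseline_bench(co, seed = 3,
                          gp_config = gp_config(population_size = 20,
                                                generations = 3),
                          learners = c("Linear Regression", "Random Forest"))
  expect_equal(bench[bench$model %in% again$model, ], again,
               ignore_attr = TRUE)
})

test_that("the seven-measure suite normalizes each measure to 100 and agrees on a dominant signal", {
  spec <- synthetic_spec(n = 150, p = 6,
                         signal_vars = list(list(index = 2, kind = "linear",
                                                 effect = 3)),
                         collinear_pairs = list(), missing_rate = 0,
                         noise_sd = 0.3, seed = 14)
  co <- generate_cohort(spec)$cohort
  ml <- setNames(c(10, 60, 10, 10, 5, 5), names(co$predictors))
  suite <- importance_suite(co, ml, seed = 5)
  measure_cols <- setdiff(names(suite), "variable")
  for (cl in measure_cols) {
    expect_equal(sum(suite[[cl]]), 100, tolerance = 1e-9)
  }
  for (cl in measure_cols) {
    expect_equal(suite$variable[which.max(suite[[cl]])], "v02")
  }
})

test_that("the approximate MIC separates strong dependence from independence", {
  set.seed(33)
  x <- rnorm(200)
  expect_gt(mic_score(x, x^2), 0.5)        # strong nonlinear dependence
  expect_lt(mic_score(x, rnorm(200)), 0.25) # independence
  expect_equal(mic_score(rep(1, 50), rnorm(50)), 0)  # constant predictor
})
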