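test_that("point-biserial correlation is the Pearson correlation with a 0/1 coding", {
  expect_equal(point_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1)), 2 / sqrt(5),
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:25) {
    x <- rnorm(30)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(point_biserial(x, y), cor(x, y))
  }
  expect_error(point_biserial(rep(1, 10), rbinom(10, 1, 0.5)), "constant")
  expect_error(point_biserial(rnorm(5), rep(1, 5)), "both classes")
})

test_that("the concordance statistic counts pairs with ties at one half", {
  expect_equal(c_statistic(c(0, 1, 0, 1), c(0.2, 0.4, 0.6, 0.8)), 0.75)
  expect_equal(c_statistic(c(0, 1, 1, 0), rep(0.3, 4)), 0.5)
  expect_equal(c_statistic(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  set.seed(42)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(30)  # continuous: tie-free almost surely
    expect_equal(c_statistic(y, s) + c_statistic(y, -s), 1)
  }
  expect_error(c_statistic(rep(1, 5), rnorm(5)), "both classes")
})

test_that("group comparisons pick the declared test per variable kind", {
  # positives are exact copies of negatives: every p-value is 1
  base <- data.frame(cont = c(1.2, 3.4, 2.2, 5.1, 4.0),
                     skew = c(0.1, 9, 0.4, 2, 7),
                     bin = c(0, 1, 0, 1, 1))
  df <- rbind(base, base)
  maxgd <- rep(c(200, 300), each = 5)
  schema <- make_schema(
    variable_spec("cont", "continuous"),
    variable_spec("skew", "continuous", skewed = TRUE),
    variable_spec("bin", "binary"),
    variable_spec("MaxGD", role = "target", allow_missing = FALSE))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(cbind(df, MaxGD = maxgd), path, row.names = FALSE)
  co <- load_cohort(path, schema)
  unlink(path)
  gc_tab <- group_compare(co)
  expect_identical(gc_tab$test, c("unpaired t", "Mann-Whitney U", "Fisher exact"))
  expect_true(all(gc_tab$p_value > 0.99))
})

test_that("a perfectly concentrated 2x2 table yields the closed-form Fisher p", {
  bin <- rep(c(1, 0), each = 10)
  maxgd <- rep(c(300, 200), each = 10)
  co <- manual_cohort(data.frame(flag = bin, other = rnorm(20)), maxgd)
  gc_tab <- group_compare(co)
  row <- gc_tab[gc_tab$variable == "flag", ]
  expect_identical(row$test, "Fisher exact")
  expect_equal(row$p_value, 2 / choose(20, 10), tolerance = 1e-9)
})

test_that("logistic fits reproduce the 2x2 odds ratio and null-model identities", {
  # exposed: 8 events / 3 non-events; unexposed: 7 / 25
  x <- rep(c(1, 0), c(11, 32))
  y <- rep(c(1, 0, 1, 0), c(8, 3, 7, 25))
  set.seed(43)
  co <- manual_cohort(data.frame(exposure = x, n1 = seq_len(43) %% 7,
                                 n2 = rnorm(43), n3 = runif(43)),
                      ifelse(y == 1, 300, 200))
  fit <- suppressWarnings(fit_logistic(co, "exposure"))
  expect_equal(unname(fit$odds_ratio["exposure"]), (8 * 25) / (3 * 7),
               tolerance = 1e-6)
  expect_true(fit$converged)
  null_fit <- fit_logistic(co, character(0))
  expect_equal(null_fit$pseudo_r2, 0)
  expect_equal(null_fit$c_statistic, 0.5)
  expect_warning(fit_logistic(co, c("exposure", "n1", "n2", "n3")),
                 "events-per-variable")
})

test_that("McFadden pseudo-R2 is invariant to affine predictor rescaling", {
  co <- tiny_cohort(seed = 15, n = 40, p = 4)
  f1 <- fit_logistic(co, c("v01", "v02"))
  co2 <- co
  co2$predictors$v01 <- co2$predictors$v01 * 1000 + 5
  f2 <- fit_logistic(co2, c("v01", "v02"))
  expect_equal(f1$pseudo_r2, f2$pseudo_r2, tolerance = 1e-6)
  expect_equal(f1$c_statistic, f2$c_statistic, tolerance = 1e-6)
})

test_that("complete separation is flagged rather than silently reported", {
  x <- c(rnorm(10, -3), rnorm(10, 3))
  co <- manual_cohort(data.frame(sep = x, z = rnorm(20)),
                      ifelse(x > 0, 300, 200))
  expect_warning(fit <- fit_logistic(co, "sep"), "converge|separation")
  expect_false(fit$converged)
})

test_that("linear fits recover exact relations and standardized coefficients", {
  x <- seq(1, 5, length.out = 30)
  co <- manual_cohort(data.frame(x = x, w = rnorm(30)), 100 + 2 * x * 30)
  fit <- fit_linear(co, "x")
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(unname(fit$std_beta["x"]), 1, tolerance = 1e-9)
  # standardized beta equals the coefficient of the z-scored regression
  co2 <- tiny_cohort(seed = 16, n = 35, p = 5)
  fit2 <- fit_linear(co2, c("v01", "v02", "v03"))
  Z <- scale(co2$predictors[, c("v01", "v02", "v03")])
  zfit <- lm(scale(co2$maxgd) ~ Z)
  expect_equal(unname(fit2$std_beta), unname(coef(zfit)[-1]), tolerance = 1e-9)
  expect_error(fit_linear(co2, character(0)))
})

test_that("AICc applies the small-sample correction and vanishes asymptotically", {
  expect_equal(aicc(-10, 3, 20), 20 + 6 + 2 * 3 * 4 / 16)
  expect_equal(aicc(-10, 3, 1e7) - (20 + 6), 0, tolerance = 1e-5)
  expect_warning(val <- aicc(-10, 9, 10), "undefined")
  expect_identical(val, Inf)
})

test_that("VIFs match their closed form and an independent implementation", {
  set.seed(44)
  # columns orthogonal to each other and to the intercept via QR
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 3), 200))))[, -1]
  expect_equal(unname(compute_vif(Q)), rep(1, 3), tolerance = 1e-9)
  # two predictors: VIF = 1 / (1 - r^2)
  x1 <- rnorm(100)
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(100)
  v <- compute_vif(cbind(x1, x2))
  r2 <- cor(x1, x2)^2
  expect_equal(unname(v), rep(1 / (1 - r2), 2), tolerance = 1e-9)
  expect_equal(unname(v)[1], 2.78, tolerance = 0.6)  # near the theoretical 2.78
  # cross-check against car::vif on a larger random design
  skip_if_not_installed("car")
  X <- matrix(rnorm(80 * 5), 80)
  X[, 5] <- X[, 1] * 0.7 + rnorm(80, sd = 0.5)
  colnames(X) <- paste0("c", 1:5)
  y <- rnorm(80)
  dat <- data.frame(y = y, X)
  car_v <- car::vif(lm(y ~ ., data = dat))
  expect_equal(unname(compute_vif(X)), unname(car_v), tolerance = 1e-8)
  # duplicated column: infinite VIF flagged
  expect_warning(vdup <- compute_vif(cbind(x1, x1)), "collinear")
  expect_true(any(!is.finite(vdup)))
})

test_that("linear model VIFs respond to an appended collinear term", {
  co <- tiny_cohort(seed = 17, n = 40, p = 5)
  co$predictors$v05 <- co$predictors$v01 + rnorm(40, sd = 0.05)
  f_clean <- fit_linear(co, c("v02", "v03"))
  f_coll <- fit_linear(co, c("v01", "v05", "v02"))
  expect_lt(max(f_clean$vif), 2)
  expect_gt(max(f_coll$vif), 10)
  expect_equal(f_coll$vif_threshold, 1 / (1 - f_coll$r2), tolerance = 1e-12)
})

test_that("correlation ranking orders by absolute point-biserial r", {
  co <- tiny_cohort(seed = 18, n = 60, p = 6)
  cr <- correlation_ranking(co)
  expect_identical(cr$variable[1], "v01")  # the planted signal
  expect_true(all(diff(cr$abs_r) <= 1e-12))
  expect_equal(cr$abs_r, abs(cr$r))
})
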