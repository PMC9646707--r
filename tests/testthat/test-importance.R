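archive_of <- function(models, totals = length(models)) {
  srgprank:::new_archive(models, totals = totals)
}

test_that("suitable-model selection lands in the band and keeps the first front", {
  set.seed(21)
  for (i in 1:30) {
    m <- sample(100:400, 1)
    arch <- archive_of(random_models(m))
    sel <- select_suitable_models(arch, 0.08, 0.20)
    lo <- ceiling(0.08 * m)
    hi <- floor(0.20 * m)
    expect_gte(length(sel), lo)
    expect_lte(length(sel), hi)
    front <- pareto_front(arch$models)
    if (length(front) <= hi) {
      expect_true(all(vapply(front, model_key, character(1)) %in%
                        vapply(sel, model_key, character(1))))
    }
  }
})

test_that("a fully non-dominated archive is truncated to the upper band edge", {
  # strictly decreasing error with increasing complexity: nothing dominates
  models <- lapply(1:100, function(i) {
    list(complexity = i, train_error = 1 - i / 200, used_vars = "v01",
         tree = gp_const_tree(i))
  })
  arch <- archive_of(models)
  sel <- select_suitable_models(arch, 0.08, 0.20)
  expect_length(sel, 20)
  expect_true(all(vapply(sel, `[[`, numeric(1), "train_error") <=
                    sort(vapply(models, `[[`, numeric(1), "train_error"))[20]))
})

test_that("archives below the band minimum are returned whole with a warning", {
  arch <- archive_of(random_models(5), totals = 500)
  expect_warning(sel <- select_suitable_models(arch, 0.08, 0.20), "smaller")
  expect_length(sel, 5)
})

test_that("variable frequencies match the brute-force membership count", {
  set.seed(22)
  vars <- sprintf("v%02d", 1:8)
  for (i in 1:40) {
    sel <- random_models(sample(10:60, 1), vars)
    expect_equal(variable_frequencies(sel, vars), frequency_oracle(sel, vars))
  }
  sel <- random_models(20, vars)
  for (m in seq_along(sel)) sel[[m]]$used_vars <- union(sel[[m]]$used_vars, "v01")
  expect_equal(unname(variable_frequencies(sel, vars)["v01"]), 100)
})

test_that("ML scores normalize frequencies to a 100-point budget", {
  f <- c(a = 40, b = 0, c = 10)
  s <- ml_scores(f)
  expect_equal(sum(s), 100)
  expect_equal(unname(s), c(80, 0, 20))
  expect_equal(unname(ml_scores(c(a = 7, b = 0))), c(100, 0))
  expect_error(ml_scores(c(a = 0, b = 0)), "all frequencies are zero")
  set.seed(3)
  for (i in 1:20) {
    f <- runif(10) * rbinom(10, 1, 0.7)
    if (sum(f) == 0) f[1] <- 1
    s <- ml_scores(f)
    expect_equal(sum(s), 100, tolerance = 1e-9)
    nz <- f > 0
    expect_equal(s[nz] / f[nz], rep((100 / sum(f)), sum(nz)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("dominant variables use a strict threshold and descending order", {
  f <- c(bmi = 82.9, c3 = 72.2, tp = 5.0, ox = 6.8, bw = 3.4)
  expect_identical(dominant_variables(f, 5), c("bmi", "c3", "ox"))
  expect_identical(dominant_variables(c(a = 1, b = 2), 5), character(0))
  set.seed(4)
  for (i in 1:20) {
    f <- setNames(runif(12, 0, 20), sprintf("x%02d", 1:12))
    got <- dominant_variables(f, 5)
    want <- names(sort(f[f > 5], decreasing = TRUE))
    expect_identical(got, want)
  }
})

test_that("frequency and score rankings coincide and selection is scale-free", {
  set.seed(23)
  vars <- sprintf("v%02d", 1:8)
  arch <- archive_of(random_models(200, vars))
  tab <- importance_table(arch, vars)
  expect_identical(tab$freq_rank, tab$score_rank)
  expect_equal(sum(tab$ml_score), 100, tolerance = 1e-9)
  # duplicating every model leaves the frequencies unchanged
  doubled <- archive_of(c(arch$models, arch$models), totals = 2 * arch$totals)
  tab2 <- importance_table(doubled, vars)
  expect_equal(tab2$frequency[match(tab$variable, tab2$variable)],
               tab$frequency, tolerance = 1e-9)
})
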