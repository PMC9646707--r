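vtree <- function(name) list(t = "v", name = name)
ctree <- function(v) list(t = "c", value = v)
otree <- function(op, l, r = NULL) {
  if (op == "sqrt") list(t = "o", op = "sqrt", l = l)
  else list(t = "o", op = op, l = l, r = r)
}

test_that("tree evaluation follows arithmetic and the protected conventions", {
  rows <- data.frame(x1 = c(1, 4), x2 = c(3, 0), x3 = c(7, -2))
  expect_equal(evaluate_tree(vtree("x3"), rows), c(7, -2))
  half_sum <- otree("/", otree("+", vtree("x1"), vtree("x2")), ctree(2))
  expect_equal(evaluate_tree(half_sum, rows), c(2, 2))
  # protected division: denominator 0 -> 1; protected sqrt of a negative
  expect_equal(evaluate_tree(otree("/", vtree("x1"), vtree("x2")), rows),
               c(1 / 3, 1))
  expect_equal(evaluate_tree(otree("sqrt", vtree("x3")), rows),
               c(sqrt(7), sqrt(2)))
  expect_error(evaluate_tree(vtree("zz"), rows), "unknown variable")
})

test_that("random trees stay finite on finite inputs", {
  set.seed(42)
  rows <- data.frame(a = rnorm(30, sd = 100), b = c(0, rnorm(29)),
                     c = runif(30, -1e6, 1e6))
  cfg <- gp_config(seed = 1)
  for (i in 1:60) {
    tr <- srgprank:::rand_tree(names(rows), cfg, 6)
    expect_true(all(is.finite(evaluate_tree(tr, rows))))
  }
})

test_that("complexity is visitation length and grows with any added node", {
  expect_equal(tree_complexity(vtree("x1")), 1L)
  expect_equal(tree_complexity(ctree(3)), 1L)
  expect_equal(tree_complexity(otree("+", vtree("x1"), vtree("x2"))), 5L)
  expect_equal(tree_complexity(otree("sqrt", vtree("x1"))), 3L)
  base <- otree("+", vtree("x1"), vtree("x2"))
  grown <- otree("+", otree("sqrt", vtree("x1")), vtree("x2"))
  expect_gt(tree_complexity(grown), tree_complexity(base))
})

test_that("the Pareto front matches exhaustive dominance and ignores input order", {
  set.seed(7)
  ms <- list(list(complexity = 3, train_error = 0.2),
             list(complexity = 5, train_error = 0.1),
             list(complexity = 4, train_error = 0.3))
  front <- pareto_front(ms)
  expect_setequal(vapply(front, model_key, character(1)),
                  c("3|0.2", "5|0.1"))
  for (i in 1:20) {
    ms <- random_models(40)
    expect_setequal(vapply(pareto_front(ms), model_key, character(1)),
                    vapply(pareto_oracle(ms), model_key, character(1)))
    shuffled <- ms[sample(length(ms))]
    expect_setequal(vapply(pareto_front(shuffled), model_key, character(1)),
                    vapply(pareto_front(ms), model_key, character(1)))
  }
  single <- random_models(1)
  expect_identical(pareto_front(single), single)
})

test_that("no front member is strictly dominated", {
  set.seed(8)
  for (i in 1:10) {
    ms <- random_models(100)
    front <- pareto_front(ms)
    cx <- vapply(ms, `[[`, numeric(1), "complexity")
    err <- vapply(ms, `[[`, numeric(1), "train_error")
    for (f in front) {
      expect_false(any(cx < f$complexity & err < f$train_error))
    }
  }
})

test_that("evolution is deterministic, monotone under elitism, and self-consistent", {
  co <- tiny_cohort(seed = 5, n = 24, p = 5)
  X <- co$predictors
  y <- co$gh_label
  cfg <- gp_config(population_size = 40, generations = 8, seed = 31)
  a1 <- evolve(X, y, cfg)
  a2 <- evolve(X, y, cfg)
  expect_identical(lapply(a1$models, `[[`, "tree"),
                   lapply(a2$models, `[[`, "tree"))
  expect_identical(a1$best_trace, a2$best_trace)
  expect_true(all(diff(a1$best_trace) <= 1e-12))
  for (m in a1$models[seq(1, 40, by = 7)]) {
    expect_equal(srgprank:::model_train_error(m, X, y), m$train_error,
                 tolerance = 1e-9)
    expect_setequal(m$used_vars, tree_vars(m$tree))
    expect_identical(tree_complexity(m$tree), m$complexity)
  }
  expect_error(evolve(X, rep(1, nrow(X)), cfg), "constant target")
})

test_that("an exactly representable target is recovered essentially noise-free", {
  set.seed(12)
  X <- data.frame(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
  arch <- evolve(X, X$x1, gp_config(population_size = 200, generations = 50,
                                    seed = 3))
  errs <- vapply(arch$models, `[[`, numeric(1), "train_error")
  expect_lte(min(errs), 0.01)
  arch2 <- evolve(X, X$x1 + X$x2, gp_config(population_size = 200,
                                            generations = 50, seed = 4))
  errs2 <- vapply(arch2$models, `[[`, numeric(1), "train_error")
  best <- arch2$models[[which.min(errs2)]]
  if (min(errs2) <= 0.01) {
    expect_true(all(best$used_vars %in% c("x1", "x2")))
  }
})

test_that("trimmed-mean ensembling drops the declared tails", {
  rows <- data.frame(x = 1)
  expect_equal(ensemble_predict(lapply(c(0.7, 0.7, 0.7), const_model), rows, 0.1),
               0.7)
  expect_equal(ensemble_predict(lapply(c(0, 0.5, 1), const_model), rows, 0), 0.5)
  expect_equal(ensemble_predict(lapply(c(0, 0.4, 0.5, 0.6, 10), const_model),
                                rows, 0.2), 0.5)
  expect_error(ensemble_predict(list(), rows), "empty model list")
})

test_that("archives round-trip through JSON lines", {
  co <- tiny_cohort(seed = 6, n = 15, p = 4)
  arch <- evolve(co$predictors, co$gh_label,
                 gp_config(population_size = 15, generations = 3, seed = 2))
  path <- tempfile(fileext = ".jsonl")
  write_archive(arch, path)
  back <- read_archive(path)
  expect_equal(back$totals, arch$totals)
  expect_equal(lapply(back$models, `[[`, "tree"),
               lapply(arch$models, `[[`, "tree"))
  expect_equal(vapply(back$models, `[[`, numeric(1), "train_error"),
               vapply(arch$models, `[[`, numeric(1), "train_error"))
  unlink(path)
})
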