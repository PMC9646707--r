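# Fixtures built in code: small cohorts, random model archives, and
# brute-force oracles used to cross-check the fast implementations.

# small complete synthetic cohort for fast unit tests
tiny_cohort <- function(seed = 1, n = 20, p = 6) {
  spec <- synthetic_spec(
    n = n, p = p,
    signal_vars = list(list(index = 1, kind = "linear", effect = 1.2)),
    collinear_pairs = list(),
    missing_rate = 0, prevalence = 0.4, seed = seed)
  generate_cohort(spec)$cohort
}

# cohort built from explicit values (schema inferred)
manual_cohort <- function(predictors, maxgd, threshold = GH_THRESHOLD) {
  df <- as.data.frame(predictors)
  df$MaxGD <- maxgd
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  on.exit(unlink(path))
  load_cohort(path, threshold = threshold)
}

# random candidate-model stubs (no trees needed for Pareto / frequency logic)
random_models <- function(m, vars = sprintf("v%02d", 1:8)) {
  lapply(seq_len(m), function(i) {
    list(complexity = sample(1:30, 1),
         train_error = round(runif(1, 0, 1.5), 3),
         used_vars = sample(vars, sample.int(length(vars), 1)),
         tree = gp_const_tree(i))
  })
}

gp_const_tree <- function(v) list(t = "c", value = v)

# model stub whose ensemble prediction is the constant v
const_model <- function(v) {
  list(tree = list(t = "c", value = v), complexity = 1L, train_error = 1,
       scale = c(a = 0, b = 1), used_vars = character(0))
}

# O(m^2) exhaustive dominance oracle for the Pareto front
pareto_oracle <- function(models) {
  cx <- vapply(models, `[[`, numeric(1), "complexity")
  err <- vapply(models, `[[`, numeric(1), "train_error")
  keep <- vapply(seq_along(models), function(i) {
    !any(cx <= cx[i] & err <= err[i] & (cx < cx[i] | err < err[i]))
  }, logical(1))
  models[keep]
}

# brute-force per-model membership count for variable frequencies
frequency_oracle <- function(selected, all_vars) {
  vapply(all_vars, function(v) {
    100 * sum(vapply(selected, function(m) v %in% m$used_vars, logical(1))) /
      length(selected)
  }, numeric(1))
}

model_key <- function(m) paste(m$complexity, m$train_error, sep = "|")
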