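# Symbolic-regression engine: expression trees over the building blocks
# {+, -, *, /, sqrt} plus variables and constants, evolved by genetic
# programming against 1 - R^2 with a complexity/accuracy Pareto archive.

GP_BINARY_OPS <- c("+", "-", "*", "/")

#' Genetic-programming configuration
#'
#' Hyperparameters of the evolutionary search. None of these are dictated by
#' the method itself; the defaults are conventional tree-GP settings sized for
#' cohorts of a few dozen subjects.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate Probability an offspring is produced by subtree
#'   crossover (otherwise it clones a tournament winner).
#' @param mutation_rate Probability an offspring is additionally mutated.
#' @param constant_range Range for ephemeral numeric constants.
#' @param max_depth Maximum depth of freshly grown trees; evolved trees may
#'   exceed it by a small fixed slack before offspring are rejected.
#' @param elitism_count Number of best-by-error individuals copied unchanged
#'   into the next generation.
#' @param tournament_size Tournament size for parent selection.
#' @param parsimony_coef Weight of complexity added to the error during
#'   selection (parsimony pressure); fitness for archiving is the raw error.
#' @param sqrt_weight Probability that a grown internal node is the unary
#'   square root rather than a binary operator.
#' @param seed Integer seed; evolution is fully deterministic given it.
#' @return A `gp_config` list.
#' @export
gp_config <- function(population_size = 500, generations = 50,
                      crossover_rate = 0.9, mutation_rate = 0.15,
                      constant_range = c(-5, 5), max_depth = 6,
                      elitism_count = 1, tournament_size = 3,
                      parsimony_coef = 1e-3, sqrt_weight = 0.1, seed = 1) {
  stopifnot(population_size >= 2, generations >= 1, max_depth >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism_count >= 0, tournament_size >= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 constant_range = constant_range, max_depth = as.integer(max_depth),
                 elitism_count = as.integer(elitism_count),
                 tournament_size = as.integer(tournament_size),
                 parsimony_coef = parsimony_coef, sqrt_weight = sqrt_weight,
                 seed = as.integer(seed)),
            class = "gp_config")
}

# --- tree constructors ----------------------------------------------------

gp_var <- function(name) list(t = "v", name = name)
gp_const <- function(value) list(t = "c", value = value)
gp_op <- function(op, l, r = NULL) {
  if (op == "sqrt") list(t = "o", op = "sqrt", l = l)
  else list(t = "o", op = op, l = l, r = r)
}

tree_kids <- function(tr) {
  if (tr$t != "o") return(list())
  if (tr$op == "sqrt") list(tr$l) else list(tr$l, tr$r)
}

# node count and visitation length in one pass: c(size, visitation)
tree_stats <- function(tr) {
  if (tr$t != "o") return(c(1, 1))
  sl <- tree_stats(tr$l)
  if (tr$op == "sqrt") {
    size <- 1 + sl[1]
    c(size, size + sl[2])
  } else {
    sr <- tree_stats(tr$r)
    size <- 1 + sl[1] + sr[1]
    c(size, size + sl[2] + sr[2])
  }
}

tree_size <- function(tr) tree_stats(tr)[1]

#' Model complexity of an expression tree
#'
#' Visitation length: the sum over all nodes of the size of the subtree rooted
#' at that node. It grows strictly when any node is added, and penalizes depth
#' and size jointly. A single leaf has complexity 1; `x1 + x2` has complexity
#' 5; `sqrt(x1)` has complexity 3.
#'
#' @param tree An expression tree.
#' @return A positive integer.
#' @export
tree_complexity <- function(tree) as.integer(tree_stats(tree)[2])

tree_depth <- function(tr) {
  if (tr$t != "o") return(1L)
  1L + max(vapply(tree_kids(tr), tree_depth, integer(1)))
}

#' Variables referenced by a tree
#' @param tree An expression tree.
#' @return Character vector of unique variable names.
#' @export
tree_vars <- function(tree) {
  if (tree$t == "v") return(tree$name)
  if (tree$t == "c") return(character(0))
  unique(unlist(lapply(tree_kids(tree), tree_vars)))
}

# --- evaluation -----------------------------------------------------------

# protected division: elementwise 1 wherever |denominator| < 1e-12
pdiv <- function(a, b) {
  r <- a / b
  bad <- rep_len(abs(b) < 1e-12, length(r))
  if (any(bad)) r[bad] <- 1
  r
}

# protected square root: operates on the absolute value
psqrt <- function(a) sqrt(abs(a))

tree_call <- function(tr) {
  switch(tr$t,
    v = as.name(tr$name),
    c = tr$value,
    o = if (tr$op == "sqrt") {
      call("psqrt", tree_call(tr$l))
    } else if (tr$op == "/") {
      call("pdiv", tree_call(tr$l), tree_call(tr$r))
    } else {
      call(tr$op, tree_call(tr$l), tree_call(tr$r))
    })
}

make_eval_env <- function(dat) {
  fns <- new.env(parent = baseenv())
  fns$pdiv <- pdiv
  fns$psqrt <- psqrt
  list2env(as.list(dat), envir = new.env(parent = fns))
}

# clamp to a large finite magnitude; NaN (e.g. Inf - Inf) maps to 0
finite_clamp <- function(res, n) {
  if (length(res) == 1L) res <- rep_len(res, n)
  res[is.nan(res)] <- 0
  res[res > 1e15] <- 1e15
  res[res < -1e15] <- -1e15
  res
}

#' Evaluate an expression tree on tabular rows
#'
#' Elementwise evaluation with protected operators: division returns 1
#' wherever the denominator's magnitude is below `1e-12`, and the square root
#' acts on the absolute value. The result is clamped to a large finite
#' magnitude, so finite inputs always yield finite outputs.
#'
#' @param tree An expression tree.
#' @param rows A data frame or named matrix whose columns cover
#'   `tree_vars(tree)`.
#' @return Numeric vector, one value per row.
#' @export
evaluate_tree <- function(tree, rows) {
  dat <- as.data.frame(rows)
  needed <- tree_vars(tree)
  absent <- setdiff(needed, names(dat))
  if (length(absent)) {
    stop("tree references unknown variable(s): ", paste(absent, collapse = ", "))
  }
  env <- make_eval_env(dat)
  finite_clamp(eval(tree_call(tree), env), nrow(dat))
}

#' Render a tree as an infix formula string
#' @param tree An expression tree.
#' @return A character scalar, e.g. `"(v01 + sqrt(v03))"`.
#' @export
format_tree <- function(tree) {
  switch(tree$t,
    v = tree$name,
    c = format(tree$value, digits = 6),
    o = if (tree$op == "sqrt") {
      paste0("sqrt(", format_tree(tree$l), ")")
    } else {
      paste0("(", format_tree(tree$l), " ", tree$op, " ", format_tree(tree$r), ")")
    })
}

# --- random trees and genetic operators -----------------------------------

rand_terminal <- function(vars, cfg) {
  if (stats::runif(1) < 0.7) {
    gp_var(vars[sample.int(length(vars), 1L)])
  } else {
    gp_const(stats::runif(1, cfg$constant_range[1], cfg$constant_range[2]))
  }
}

rand_tree <- function(vars, cfg, depth) {
  if (depth <= 1L || stats::runif(1) < 0.25) {
    return(rand_terminal(vars, cfg))
  }
  if (stats::runif(1) < cfg$sqrt_weight) {
    gp_op("sqrt", rand_tree(vars, cfg, depth - 1L))
  } else {
    op <- GP_BINARY_OPS[sample.int(4L, 1L)]
    gp_op(op, rand_tree(vars, cfg, depth - 1L), rand_tree(vars, cfg, depth - 1L))
  }
}

# preorder subtree extraction (k-th node, 1-based)
get_subtree <- function(tr, k) {
  if (k == 1L) return(list(node = tr, used = 1L))
  used <- 1L
  for (kid in tree_kids(tr)) {
    res <- get_subtree(kid, k - used)
    if (!is.null(res$node)) return(list(node = res$node, used = used + res$used))
    used <- used + res$used
  }
  list(node = NULL, used = used)
}

# preorder subtree replacement; returns list(tree, used)
set_subtree <- function(tr, k, new) {
  if (k == 1L) return(list(tree = new, used = 1L))
  used <- 1L
  kids <- tree_kids(tr)
  for (i in seq_along(kids)) {
    res <- set_subtree(kids[[i]], k - used, new)
    used <- used + res$used
    if (!is.null(res$tree)) {
      if (i == 1L) tr$l <- res$tree else tr$r <- res$tree
      return(list(tree = tr, used = used))
    }
  }
  list(tree = NULL, used = used)
}

crossover_trees <- function(t1, t2) {
  i <- sample.int(tree_size(t1), 1L)
  j <- sample.int(tree_size(t2), 1L)
  donor <- get_subtree(t2, j)$node
  set_subtree(t1, i, donor)$tree
}

mutate_tree <- function(tr, vars, cfg) {
  if (stats::runif(1) < 0.5) {
    # point mutation at a random node
    k <- sample.int(tree_size(tr), 1L)
    node <- get_subtree(tr, k)$node
    new <- if (node$t == "c") {
      gp_const(node$value + stats::rnorm(1))
    } else if (node$t == "v") {
      gp_var(vars[sample.int(length(vars), 1L)])
    } else if (node$op == "sqrt") {
      node
    } else {
      node$op <- GP_BINARY_OPS[sample.int(4L, 1L)]
      node
    }
    set_subtree(tr, k, new)$tree
  } else {
    # subtree mutation: replace a random node with a freshly grown tree
    k <- sample.int(tree_size(tr), 1L)
    set_subtree(tr, k, rand_tree(vars, cfg, 3L))$tree
  }
}

# --- evolution ------------------------------------------------------------

new_archive <- function(models, totals = length(models), best_trace = NULL) {
  structure(list(models = models, totals = as.integer(totals),
                 best_trace = best_trace),
            class = "srg_archive")
}

#' Merge model archives
#' @param ... `srg_archive` objects (or a single list of them).
#' @return One archive whose `totals` is the sum of the parts.
#' @export
merge_archives <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "srg_archive")) {
    parts <- parts[[1]]
  }
  new_archive(do.call(c, lapply(parts, `[[`, "models")),
              totals = sum(vapply(parts, `[[`, integer(1), "totals")))
}

#' @export
print.srg_archive <- function(x, ...) {
  errs <- vapply(x$models, `[[`, numeric(1), "train_error")
  cat(sprintf("srg_archive: %d models retained (of %d generated)\n",
              length(x$models), x$totals))
  if (length(errs)) {
    cat(sprintf("  train error (1 - R^2): min %.4f, median %.4f\n",
                min(errs), stats::median(errs)))
  }
  invisible(x)
}

#' Evolve an archive of symbolic-regression models
#'
#' Runs tree-based genetic programming against the training target. Fitness
#' is `1 - R^2` (the coefficient of determination) of the tree output after
#' optimal affine calibration `y ~ a + b * tree(x)` — linear-scaling
#' fitness, the standard device by which symbolic regression searches the
#' form of the function while the outer scale and offset are solved exactly
#' rather than evolved. The calibration pair `(a, b)` is stored with each
#' model and applied at prediction time. For a dichotomous 0/1 target this
#' is regression on the class indicator; the 0.5 classification threshold is
#' applied only at prediction time. Errors are clipped to `[0, 1.5]` so
#' degenerate models cannot distort the Pareto geometry (a constant tree
#' scores exactly 1). Selection is by tournament on error plus a small
#' complexity penalty (parsimony pressure); elitism copies the best
#' individuals by raw error, so the per-generation best error is
#' non-increasing. The final generation is retained as the model archive.
#'
#' @param x Data frame or named matrix of predictors (complete rows).
#' @param y Numeric target (continuous, or the 0/1 class indicator). Must not
#'   be constant.
#' @param config A [gp_config()].
#' @param provenance Optional named integer vector (`trial`, `fold`,
#'   `species`) recorded on every archived model.
#' @return An `srg_archive` with one `CandidateModel` per retained model:
#'   `tree`, `complexity`, `train_error`, `used_vars`, `provenance`. The
#'   archive also carries `best_trace`, the best raw error per generation.
#' @export
evolve <- function(x, y, config = gp_config(),
                   provenance = c(trial = 1L, fold = 0L, species = 1L)) {
  x <- as.data.frame(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) >= 2, length(y) == nrow(x))
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("degenerate constant target: R^2 is undefined")
  vars <- names(x)
  env <- make_eval_env(x)
  n <- nrow(x)
  ybar <- mean(y)

  # 1 - R^2 under the optimal affine calibration a + b * pred
  fit_err <- function(cl) {
    pred <- finite_clamp(eval(cl, env), n)
    pbar <- mean(pred)
    spp <- sum((pred - pbar)^2)
    if (spp < 1e-12) return(list(err = 1, a = ybar, b = 0))
    b <- sum((pred - pbar) * (y - ybar)) / spp
    a <- ybar - b * pbar
    err <- sum((y - (a + b * pred))^2) / sst
    list(err = min(max(err, 0), 1.5), a = a, b = b)
  }
  make_ind <- function(tree) {
    cl <- tree_call(tree)
    st <- tree_stats(tree)
    fe <- fit_err(cl)
    list(tree = tree, size = st[1], cx = as.integer(st[2]), err = fe$err,
         scale = c(a = fe$a, b = fe$b))
  }

  set.seed(config$seed)
  # ramped initial depths between 2 and max_depth
  depths <- rep_len(seq.int(2L, max(2L, config$max_depth)), config$population_size)
  pop <- lapply(depths, function(d) make_ind(rand_tree(vars, config, d)))
  depth_cap <- config$max_depth + 4L
  best_trace <- numeric(config$generations)

  for (gen in seq_len(config$generations)) {
    errs <- vapply(pop, `[[`, numeric(1), "err")
    sel_fit <- errs + config$parsimony_coef *
      vapply(pop, `[[`, numeric(1), "cx")
    tournament <- function() {
      idx <- sample.int(length(pop), config$tournament_size, replace = TRUE)
      idx[which.min(sel_fit[idx])]
    }
    elite_idx <- order(errs)[seq_len(min(config$elitism_count, length(pop)))]
    newpop <- pop[elite_idx]
    while (length(newpop) < config$population_size) {
      p1 <- pop[[tournament()]]
      child <- if (stats::runif(1) < config$crossover_rate) {
        crossover_trees(p1$tree, pop[[tournament()]]$tree)
      } else {
        p1$tree
      }
      if (stats::runif(1) < config$mutation_rate) {
        child <- mutate_tree(child, vars, config)
      }
      if (tree_depth(child) > depth_cap) child <- p1$tree
      newpop[[length(newpop) + 1L]] <- make_ind(child)
    }
    pop <- newpop
    best_trace[gen] <- min(vapply(pop, `[[`, numeric(1), "err"))
  }

  models <- lapply(seq_along(pop), function(i) {
    ind <- pop[[i]]
    list(tree = ind$tree, complexity = ind$cx, train_error = ind$err,
         scale = ind$scale, used_vars = tree_vars(ind$tree),
         provenance = c(as.list(provenance),
                        list(generation = config$generations, index = i)))
  })
  new_archive(models, totals = length(models), best_trace = best_trace)
}

# --- Pareto front and ensembling ------------------------------------------

#' Pareto front in the (complexity, error) plane
#'
#' Returns every model not dominated in `(complexity, train_error)`: model m
#' dominates m' when it is less than or equal in both coordinates and
#' strictly smaller in at least one. Exact ties in both coordinates are all
#' kept. The result is independent of input order (set equality).
#'
#' @param models A list of candidate models (each with `complexity` and
#'   `train_error`), or an `srg_archive`.
#' @return The non-dominated subset, as a list of models.
#' @export
pareto_front <- function(models) {
  if (inherits(models, "srg_archive")) models <- models$models
  stopifnot(length(models) >= 1)
  cx <- vapply(models, `[[`, numeric(1), "complexity")
  err <- vapply(models, `[[`, numeric(1), "train_error")
  keep <- pareto_mask(cx, err)
  models[keep]
}

# sweep over complexity groups: a point survives iff its error equals the
# group minimum and is strictly below the best error at smaller complexity
pareto_mask <- function(cx, err) {
  keep <- logical(length(cx))
  best <- Inf
  for (c_val in sort(unique(cx))) {
    grp <- which(cx == c_val)
    gmin <- min(err[grp])
    if (gmin < best) {
      keep[grp[err[grp] == gmin]] <- TRUE
      best <- gmin
    }
  }
  keep
}

#' Trimmed-mean ensemble prediction
#'
#' The optimized model is the trimmed mean of its constituents: for each row,
#' the `floor(trim_fraction * m)` lowest and highest of the m constituent
#' predictions are dropped and the rest averaged. For classification the
#' caller thresholds the ensemble value at 0.5.
#'
#' @param models Nonempty list of candidate models (or an `srg_archive`).
#' @param rows Data frame or named matrix of predictor rows.
#' @param trim_fraction Fraction trimmed from each tail, in `[0, 0.5)`.
#' @return Numeric vector of ensemble predictions, one per row.
#' @export
ensemble_predict <- function(models, rows, trim_fraction = 0.1) {
  if (inherits(models, "srg_archive")) models <- models$models
  if (!length(models)) stop("empty model list")
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  dat <- as.data.frame(rows)
  env <- make_eval_env(dat)
  n <- nrow(dat)
  preds <- vapply(models, function(m) {
    raw <- finite_clamp(eval(tree_call(m$tree), env), n)
    if (!is.null(m$scale)) raw <- m$scale[["a"]] + m$scale[["b"]] * raw
    raw
  }, numeric(n))
  preds <- matrix(preds, nrow = n)
  k <- floor(trim_fraction * length(models))
  apply(preds, 1, function(v) {
    v <- sort(v)
    if (k > 0) v <- v[(k + 1):(length(v) - k)]
    mean(v)
  })
}

# recompute a candidate model's calibrated 1 - R^2 on data (used to check
# that stored training errors match their trees)
model_train_error <- function(model, x, y) {
  pred <- evaluate_tree(model$tree, x)
  sst <- sum((y - mean(y))^2)
  pbar <- mean(pred)
  spp <- sum((pred - pbar)^2)
  if (spp < 1e-12) return(1)
  b <- sum((pred - pbar) * (y - mean(y))) / spp
  a <- mean(y) - b * pbar
  min(max(sum((y - (a + b * pred))^2) / sst, 0), 1.5)
}

# --- archive serialization (JSON lines) -----------------------------------

tree_to_plist <- function(tr) {
  switch(tr$t,
    v = tr$name,
    c = tr$value,
    o = c(list(tr$op), lapply(tree_kids(tr), tree_to_plist)))
}

plist_to_tree <- function(pl) {
  if (is.character(pl)) return(gp_var(pl))
  if (is.numeric(pl)) return(gp_const(pl))
  op <- pl[[1]]
  if (op == "sqrt") gp_op("sqrt", plist_to_tree(pl[[2]]))
  else gp_op(op, plist_to_tree(pl[[2]]), plist_to_tree(pl[[3]]))
}

#' Serialize an archive to JSON lines
#'
#' One model per line: prefix-notation tree, complexity, training error, and
#' provenance. `read_archive()` reverses it; the total generated count is
#' stored on the first line.
#'
#' @param archive An `srg_archive`.
#' @param path Output file path.
#' @return `path` invisibly (`write_archive`); an `srg_archive`
#'   (`read_archive`).
#' @export
write_archive <- function(archive, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(totals = archive$totals), auto_unbox = TRUE),
             con)
  for (m in archive$models) {
    rec <- list(tree = tree_to_plist(m$tree), complexity = m$complexity,
                train_error = m$train_error, scale = as.list(m$scale),
                provenance = m$provenance)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_archive
#' @export
read_archive <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  models <- lapply(lines[-1], function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    tree <- plist_to_tree(rec$tree)
    list(tree = tree, complexity = as.integer(rec$complexity),
         train_error = as.numeric(rec$train_error),
         scale = c(a = as.numeric(rec$scale$a), b = as.numeric(rec$scale$b)),
         used_vars = tree_vars(tree), provenance = rec$provenance)
  })
  new_archive(models, totals = header$totals)
}
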