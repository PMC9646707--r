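#' Specification for a synthetic cohort
#'
#' Describes the generative model of a small biopsy-style cohort: `n` subjects,
#' `p` mixed-type predictors, a handful of planted signal variables acting on a
#' latent score, optional collinear predictor pairs, sparse missingness, and a
#' target positive-label prevalence. Defaults emulate the study design the
#' package is built around: 43 subjects, 60 predictors, prevalence 15/43, five
#' relevant variables (two linear, one threshold, one product interaction
#' contributing both factors), one moderately collinear pair, and 2% missing
#' cells.
#'
#' @param n Subject count.
#' @param p Predictor count.
#' @param signal_vars List of planted effects; each element is a list with
#'   `index`, `kind` (`"linear"`, `"threshold"`, `"product_interaction"`),
#'   `effect` (standardized effect size), and for interactions a `partner`
#'   index.
#' @param collinear_pairs List of `list(a, b, rho)` entries: column `b` is
#'   rebuilt as `rho * a + sqrt(1 - rho^2) * noise`.
#' @param missing_rate Per-cell missingness probability (MCAR), in `[0, 1)`.
#' @param prevalence Target positive fraction, in `(0, 1)`.
#' @param binary_fraction,ordinal_fraction Fractions of the non-signal,
#'   non-collinear columns discretized post-generation to a 0/1 indicator or
#'   a 0-3 grade, mirroring the mix of clinical variable types.
#' @param noise_sd Standard deviation of the latent Gaussian noise.
#' @param seed Master seed; every column draws from its own derived stream so
#'   adding a column never perturbs existing ones.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 43, p = 60,
                           signal_vars = list(
                             list(index = 1, kind = "linear", effect = 1.0),
                             list(index = 3, kind = "linear", effect = 0.8),
                             list(index = 4, kind = "threshold", effect = 0.8),
                             list(index = 5, kind = "product_interaction",
                                  effect = 0.7, partner = 6)),
                           collinear_pairs = list(list(a = 1, b = 2, rho = 0.6)),
                           missing_rate = 0.02, prevalence = 15 / 43,
                           binary_fraction = 1 / 3, ordinal_fraction = 1 / 6,
                           noise_sd = 1, seed = 1) {
  stopifnot(n >= 2, p >= 1, missing_rate >= 0, missing_rate < 1,
            prevalence > 0, prevalence < 1)
  for (sv in signal_vars) {
    stopifnot(sv$index >= 1, sv$index <= p)
    if (identical(sv$kind, "product_interaction")) {
      stopifnot(!is.null(sv$partner), sv$partner >= 1, sv$partner <= p)
    }
  }
  for (cp in collinear_pairs) {
    stopifnot(cp$a >= 1, cp$a <= p, cp$b >= 1, cp$b <= p, abs(cp$rho) < 1)
  }
  structure(list(n = n, p = p, signal_vars = signal_vars,
                 collinear_pairs = collinear_pairs,
                 missing_rate = missing_rate, prevalence = prevalence,
                 binary_fraction = binary_fraction,
                 ordinal_fraction = ordinal_fraction,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_spec")
}

# Columns whose raw Gaussian values must stay intact for the planted effects
# and the collinearity construction to hold.
protected_columns <- function(spec) {
  idx <- integer(0)
  for (sv in spec$signal_vars) {
    idx <- c(idx, sv$index, if (!is.null(sv$partner)) sv$partner)
  }
  for (cp in spec$collinear_pairs) idx <- c(idx, cp$a, cp$b)
  sort(unique(idx))
}

# Raw Gaussian columns with collinear pairs applied; reused by the
# Monte-Carlo calibration of the label threshold.
draw_gaussian_columns <- function(spec, n, seed_offset = 100L) {
  x <- matrix(0, n, spec$p)
  for (j in seq_len(spec$p)) {
    set.seed(derive_seed(spec$seed, seed_offset, j))
    x[, j] <- stats::rnorm(n)
  }
  for (cp in spec$collinear_pairs) {
    x[, cp$b] <- cp$rho * x[, cp$a] + sqrt(1 - cp$rho^2) * x[, cp$b]
  }
  x
}

latent_signal <- function(spec, x) {
  score <- numeric(nrow(x))
  for (sv in spec$signal_vars) {
    z <- x[, sv$index]
    score <- score + switch(sv$kind,
      linear = sv$effect * z,
      # step effect scaled to unit variance: 2 * (1[z > 0] - 1/2) = sign(z)
      threshold = sv$effect * sign(z),
      product_interaction = sv$effect * z * x[, sv$partner],
      stop("unknown effect kind: ", sv$kind))
  }
  score
}

#' Generate a synthetic cohort with planted signal
#'
#' A latent score combines the planted linear, threshold, and interaction
#' effects of standardized Gaussian predictors with Gaussian noise. The score
#' is mapped affinely onto a continuous MaxGD analogue so that the fraction of
#' subjects at or above the 242.3 um dichotomization threshold converges to
#' `spec$prevalence`: the offset is calibrated once against a large
#' Monte-Carlo draw from the score distribution (deterministic given the
#' seed), not against the realized sample, so small cohorts scatter
#' binomially around the target prevalence. A declared fraction of the
#' remaining columns is then binarized or discretized to 0-3 grades, and
#' sparse missingness is applied to the predictors (never to the target).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `cohort` (an `srg_cohort`), `ground_truth`
#'   (sorted indices of the relevant variables: declared signals plus
#'   interaction partners), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  x <- draw_gaussian_columns(spec, spec$n)
  score <- latent_signal(spec, x)
  set.seed(derive_seed(spec$seed, 7))
  score <- score + spec$noise_sd * stats::rnorm(spec$n)

  # calibrate the label threshold on the score scale from a reference draw
  set.seed(derive_seed(spec$seed, 8))
  m <- 200000L
  sim <- matrix(stats::rnorm(m * max(1, length(protected_columns(spec)))), m)
  xsim <- matrix(0, m, spec$p)
  xsim[, protected_columns(spec)] <- sim[, seq_along(protected_columns(spec))]
  for (cp in spec$collinear_pairs) {
    xsim[, cp$b] <- cp$rho * xsim[, cp$a] + sqrt(1 - cp$rho^2) * xsim[, cp$b]
  }
  sim_score <- latent_signal(spec, xsim) + spec$noise_sd * stats::rnorm(m)
  q <- stats::quantile(sim_score, 1 - spec$prevalence, names = FALSE)
  scale_um <- 30.8 / stats::sd(sim_score)  # SD matched to the biopsy series
  maxgd <- GH_THRESHOLD + scale_um * (score - q)

  gh <- maxgd >= GH_THRESHOLD
  if (all(gh) || !any(gh)) {
    stop("infeasible prevalence: generated cohort has a single class at n = ",
         spec$n, "; increase n or adjust prevalence")
  }

  # discretize a fraction of the unprotected columns
  protected <- protected_columns(spec)
  free <- setdiff(seq_len(spec$p), protected)
  nb <- min(length(free), round(spec$p * spec$binary_fraction))
  no <- min(length(free) - nb, round(spec$p * spec$ordinal_fraction))
  bin_cols <- free[seq_len(nb)]
  ord_cols <- free[nb + seq_len(no)]
  kinds <- rep("continuous", spec$p)
  for (j in bin_cols) {
    set.seed(derive_seed(spec$seed, 200, j))
    cut <- stats::qnorm(stats::runif(1, 0.2, 0.8))
    x[, j] <- as.numeric(x[, j] > cut)
    kinds[j] <- "binary"
  }
  for (j in ord_cols) {
    x[, j] <- as.numeric(cut(x[, j], c(-Inf, -1, 0, 1, Inf))) - 1
    kinds[j] <- "ordinal_grade"
  }

  # sparse MCAR missingness on predictors only, at least one observed per column
  miss <- matrix(FALSE, spec$n, spec$p)
  if (spec$missing_rate > 0) {
    for (j in seq_len(spec$p)) {
      set.seed(derive_seed(spec$seed, 300, j))
      mj <- stats::runif(spec$n) < spec$missing_rate
      if (all(mj)) mj[1] <- FALSE
      miss[, j] <- mj
    }
  }
  x[miss] <- NA

  vnames <- sprintf("v%02d", seq_len(spec$p))
  colnames(x) <- vnames
  specs <- lapply(seq_len(spec$p), function(j) {
    variable_spec(vnames[j], kinds[j],
                  grade_min = if (kinds[j] == "ordinal_grade") 0 else NA_real_,
                  grade_max = if (kinds[j] == "ordinal_grade") 3 else NA_real_)
  })
  specs[[spec$p + 1]] <- variable_spec("MaxGD", "continuous", units = "um",
                                       role = "target", allow_missing = FALSE)
  schema <- make_schema(specs)
  cohort <- new_cohort(as.data.frame(x), maxgd, schema)

  gt <- sort(unique(as.integer(unlist(lapply(spec$signal_vars, function(sv) {
    c(sv$index, if (!is.null(sv$partner)) sv$partner)
  })))))
  list(cohort = cohort, ground_truth = gt, spec = spec)
}

#' Uniform random label permutations
#'
#' Each permutation is a uniform shuffle of the label vector, preserving its
#' multiset (and hence the positive count); the list is deterministic given
#' the seed.
#'
#' @param labels Binary 0/1 vector.
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return A list of `B` permuted vectors.
#' @export
permute_labels <- function(labels, B, seed = 1) {
  stopifnot(B >= 1)
  lapply(seq_len(B), function(b) {
    set.seed(derive_seed(seed, 9000, b))
    sample(labels)
  })
}
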