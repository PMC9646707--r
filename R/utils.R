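# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and integer tags.
# Multiplier kept small so seed * 69069 stays well inside the exactly
# representable double range; result always in [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  tags <- as.double(c(...))
  s <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (t in tags) {
    s <- (s * 69069 + t + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rescale a non-negative importance vector so it sums to 100.
# Negative entries (e.g. permutation importances) are floored at zero first.
normalize_to_100 <- function(v) {
  v[!is.finite(v) | v < 0] <- 0
  s <- sum(v)
  if (s <= 0) {
    stop("cannot normalize an all-zero importance vector")
  }
  100 * v / s
}

# Competition ("min") ranks on descending value.
rank_desc <- function(v) {
  as.integer(rank(-v, ties.method = "min"))
}
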