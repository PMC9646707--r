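# Suitable-model selection and frequency-based variable importance.

#' Select suitable models from an archive
#'
#' Operationalizes "neither overfitting nor underfitting" by iterated
#' non-dominated sorting: the Pareto front in (complexity, 1 - R^2) is
#' peeled off and accumulated, front after front, until the selection reaches
#' `fraction_low` of the generated total; if the last front overshoots
#' `fraction_high` of the total it is truncated by ascending training error.
#' The selected count therefore lands in the declared band (8%-20% by
#' default), and always contains the first Pareto front whenever that front
#' fits under the upper bound.
#'
#' @param archive An `srg_archive`.
#' @param fraction_low,fraction_high Selection band as fractions of
#'   `archive$totals`, `0 < fraction_low <= fraction_high < 1`.
#' @return A list of selected candidate models.
#' @export
select_suitable_models <- function(archive, fraction_low = 0.08,
                                   fraction_high = 0.20) {
  stopifnot(inherits(archive, "srg_archive"),
            fraction_low > 0, fraction_low <= fraction_high, fraction_high < 1)
  models <- archive$models
  if (!length(models)) stop("empty archive")
  lo <- ceiling(fraction_low * archive$totals)
  hi <- floor(fraction_high * archive$totals)
  if (length(models) < lo || hi < lo) {
    warning("archive smaller than the selection band minimum; returning all ",
            length(models), " models")
    return(models)
  }
  cx <- vapply(models, `[[`, numeric(1), "complexity")
  err <- vapply(models, `[[`, numeric(1), "train_error")
  remaining <- seq_along(models)
  selected <- integer(0)
  while (length(selected) < lo && length(remaining)) {
    front <- remaining[pareto_mask(cx[remaining], err[remaining])]
    if (length(selected) + length(front) > hi) {
      room <- hi - length(selected)
      front <- front[order(err[front])][seq_len(room)]
      selected <- c(selected, front)
      break
    }
    selected <- c(selected, front)
    remaining <- setdiff(remaining, front)
  }
  models[selected]
}

#' Appearance frequencies of variables across selected models
#'
#' `frequency(v)` is the percentage of selected models whose expression uses
#' variable v at least once; a model counts once per variable no matter how
#' often the variable recurs inside its tree.
#'
#' @param selected Nonempty list of candidate models.
#' @param all_vars Character vector of all variable names (zero-frequency
#'   variables are reported too).
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @export
variable_frequencies <- function(selected, all_vars) {
  stopifnot(length(selected) >= 1)
  counts <- stats::setNames(numeric(length(all_vars)), all_vars)
  for (m in selected) {
    used <- intersect(m$used_vars, all_vars)
    counts[used] <- counts[used] + 1
  }
  100 * counts / length(selected)
}

#' Machine-learning scores from appearance frequencies
#'
#' Rescales the frequency vector so all scores sum to 100; each score stays
#' proportional to its frequency and lies in `[0, 100]`.
#'
#' @param frequencies Named frequency vector (at least one nonzero entry).
#' @return Named score vector summing to 100.
#' @export
ml_scores <- function(frequencies) {
  s <- sum(frequencies)
  if (s <= 0) stop("all frequencies are zero; ML scores undefined")
  100 * frequencies / s
}

#' Dominant variables above a frequency threshold
#'
#' Variables whose appearance frequency strictly exceeds the threshold
#' (default 5%), ordered by descending frequency.
#'
#' @param frequencies Named frequency vector.
#' @param threshold Percentage threshold in `(0, 100)`.
#' @return Character vector of variable names.
#' @export
dominant_variables <- function(frequencies, threshold = 5) {
  stopifnot(threshold > 0, threshold < 100)
  keep <- frequencies > threshold
  names(sort(frequencies[keep], decreasing = TRUE))
}

#' Importance table for an archive
#'
#' Runs suitable-model selection, counts appearance frequencies, converts
#' them to ML scores, and attaches competition ranks (ties share the minimum
#' rank; rows are ordered by descending frequency with an alphabetical
#' tiebreak for display only). Frequency ranks and score ranks are identical
#' by construction since scores are proportional to frequencies.
#'
#' @param archive An `srg_archive`.
#' @param all_vars All predictor names.
#' @param fraction_low,fraction_high Selection band (see
#'   [select_suitable_models()]).
#' @return A data frame `(variable, frequency, ml_score, freq_rank,
#'   score_rank)` with attributes `n_selected` and `totals`.
#' @export
importance_table <- function(archive, all_vars, fraction_low = 0.08,
                             fraction_high = 0.20) {
  selected <- select_suitable_models(archive, fraction_low, fraction_high)
  freq <- variable_frequencies(selected, all_vars)
  score <- ml_scores(freq)
  tab <- data.frame(variable = names(freq), frequency = as.numeric(freq),
                    ml_score = as.numeric(score),
                    freq_rank = rank_desc(freq), score_rank = rank_desc(score),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$frequency, tab$variable), ]
  rownames(tab) <- NULL
  attr(tab, "n_selected") <- length(selected)
  attr(tab, "totals") <- archive$totals
  class(tab) <- c("srg_importance", "data.frame")
  tab
}

#' @export
print.srg_importance <- function(x, n = 15, ...) {
  cat(sprintf("Variable importance from %d suitable models (of %d generated)\n",
              attr(x, "n_selected"), attr(x, "totals")))
  print.data.frame(utils::head(x, n), digits = 3, row.names = FALSE)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more variables\n")
  invisible(x)
}
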