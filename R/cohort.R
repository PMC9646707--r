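#' Glomerular-hypertrophy threshold on maximal glomerular diameter
#'
#' Default dichotomization threshold for the continuous target MaxGD, in
#' micrometres. Subjects at or above it carry the positive label.
#' @export
GH_THRESHOLD <- 242.3

new_cohort <- function(predictors, maxgd, schema, threshold = GH_THRESHOLD,
                       miss = NULL, imputed = FALSE) {
  predictors <- as.data.frame(predictors)
  if (is.null(miss)) miss <- as.matrix(is.na(predictors))
  storage.mode(miss) <- "logical"
  cohort <- structure(
    list(predictors = predictors, miss = miss, schema = schema,
         maxgd = as.numeric(maxgd),
         gh_label = dichotomize_target(maxgd, threshold),
         threshold = threshold, imputed = imputed),
    class = "srg_cohort")
  validate_cohort(cohort)
}

validate_cohort <- function(cohort) {
  n <- nrow(cohort$predictors)
  if (n < 2L) stop("a cohort needs at least 2 subjects")
  if (length(cohort$maxgd) != n) stop("target length does not match subject count")
  pred_schema <- cohort$schema[cohort$schema$role != "target", , drop = FALSE]
  if (!identical(names(cohort$predictors), pred_schema$name)) {
    stop("predictor columns do not match schema: expected ",
         paste(pred_schema$name, collapse = ", "))
  }
  for (i in seq_len(nrow(pred_schema))) {
    v <- cohort$predictors[[i]]
    obs <- v[!is.na(v)]
    kind <- pred_schema$kind[i]
    if (kind == "binary" && length(obs) && !all(obs %in% c(0, 1))) {
      stop("binary column '", pred_schema$name[i], "' contains values outside {0, 1}")
    }
    if (kind == "percentage" && length(obs) && (min(obs) < 0 || max(obs) > 100)) {
      stop("percentage column '", pred_schema$name[i], "' has values outside [0, 100]")
    }
  }
  stopifnot(all(cohort$gh_label == as.integer(cohort$maxgd >= cohort$threshold)))
  cohort
}

#' Dichotomize the continuous target at a threshold
#'
#' The positive (hypertrophy) label is assigned when the value is greater
#' than *or equal to* the threshold: the lower bound is closed.
#'
#' @param maxgd Numeric vector of maximal glomerular diameters (micrometres).
#' @param threshold Dichotomization threshold; default [GH_THRESHOLD].
#' @return Integer 0/1 vector.
#' @examples
#' dichotomize_target(c(253.1, 204.9, 242.3))
#' @export
dichotomize_target <- function(maxgd, threshold = GH_THRESHOLD) {
  maxgd <- as.numeric(maxgd)
  if (any(!is.finite(maxgd))) {
    stop("target contains non-finite values at rows: ",
         paste(which(!is.finite(maxgd)), collapse = ", "))
  }
  as.integer(maxgd >= threshold)
}

#' Load a cohort from a CSV file
#'
#' Reads a comma-separated file (UTF-8, `.` decimal separator, empty cell =
#' missing) whose header must contain every schema variable. Cells that fail
#' numeric conversion raise an error naming the row and column. Row order is
#' preserved.
#'
#' @param path Path to the CSV file.
#' @param schema An `srg_schema` (from [make_schema()], [read_schema()] or
#'   [infer_schema()]); if `NULL`, the schema is inferred with target column
#'   `target`.
#' @param target Target column name used when inferring a schema.
#' @param threshold Dichotomization threshold for the target.
#' @return An `srg_cohort`.
#' @export
load_cohort <- function(path, schema = NULL, target = "MaxGD",
                        threshold = GH_THRESHOLD) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA"))
  if (is.null(schema)) {
    num <- as.data.frame(lapply(raw, function(v) suppressWarnings(as.numeric(v))))
    names(num) <- names(raw)
    schema <- infer_schema(num, target = target)
  }
  missing_cols <- setdiff(schema$name, names(raw))
  if (length(missing_cols)) {
    stop("schema error: column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  parse_col <- function(nm) {
    v <- raw[[nm]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop("parse error: non-numeric value '", v[bad[1]], "' in column '", nm,
           "', row ", bad[1])
    }
    out
  }
  target_name <- schema$name[schema$role == "target"]
  maxgd <- parse_col(target_name)
  pred_names <- schema$name[schema$role != "target"]
  predictors <- as.data.frame(lapply(pred_names, parse_col))
  names(predictors) <- pred_names
  new_cohort(predictors, maxgd, schema, threshold = threshold)
}

#' Write a cohort back to CSV
#'
#' Numeric values are written with 15 significant digits so that a
#' write-then-load round trip reproduces the cohort exactly up to
#' floating-point text representation. Missing cells are written empty.
#'
#' @param cohort An `srg_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  target_name <- cohort$schema$name[cohort$schema$role == "target"]
  df <- cohort$predictors
  # restore original missingness so imputation is not baked into the file
  for (j in seq_along(df)) df[[j]][cohort$miss[, j]] <- NA
  df[[target_name]] <- cohort$maxgd
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  out <- as.data.frame(lapply(df, fmt))
  names(out) <- names(df)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Impute missing predictor values
#'
#' Continuous and percentage columns are filled with the column median of the
#' observed values; binary and ordinal columns with the mode (ties broken
#' toward the smaller value). The target is never imputed. The missingness
#' mask is retained so downstream univariable statistics can still restrict
#' to observed values.
#'
#' @param cohort An `srg_cohort`.
#' @param strategy Imputation strategy; only `"median_mode"` is implemented.
#' @return The imputed cohort (`imputed = TRUE`).
#' @export
impute_missing <- function(cohort, strategy = "median_mode") {
  strategy <- match.arg(strategy, "median_mode")
  if (!any(cohort$miss)) {
    cohort$imputed <- TRUE
    return(cohort)
  }
  pred_schema <- cohort$schema[cohort$schema$role != "target", , drop = FALSE]
  for (j in seq_len(ncol(cohort$predictors))) {
    v <- cohort$predictors[[j]]
    obs <- v[!cohort$miss[, j]]
    if (!length(obs)) {
      stop("column '", pred_schema$name[j], "' has no observed values; cannot impute")
    }
    if (any(cohort$miss[, j])) {
      fill <- if (pred_schema$kind[j] %in% c("binary", "ordinal_grade")) {
        tab <- table(obs)
        as.numeric(names(tab)[which.max(tab)])
      } else {
        stats::median(obs)
      }
      v[cohort$miss[, j]] <- fill
      cohort$predictors[[j]] <- v
    }
  }
  cohort$imputed <- TRUE
  validate_cohort(cohort)
}

#' @export
print.srg_cohort <- function(x, ...) {
  n <- nrow(x$predictors)
  pos <- sum(x$gh_label)
  cat(sprintf("srg_cohort: %d subjects x %d predictors\n", n, ncol(x$predictors)))
  cat(sprintf("  target threshold %.1f; %d positives (%.1f%%)\n",
              x$threshold, pos, 100 * pos / n))
  cat(sprintf("  missing cells: %d (%s)\n", sum(x$miss),
              if (x$imputed) "imputed" else "not imputed"))
  invisible(x)
}

# Predictor matrix with imputation guaranteed; many downstream stages need
# complete design rows.
cohort_matrix <- function(cohort) {
  if (!cohort$imputed && any(cohort$miss)) {
    cohort <- impute_missing(cohort)
  }
  as.matrix(cohort$predictors)
}

# Predictor values with original missingness restored (for univariable tests).
cohort_observed <- function(cohort) {
  df <- cohort$predictors
  for (j in seq_along(df)) df[[j]][cohort$miss[, j]] <- NA
  df
}
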