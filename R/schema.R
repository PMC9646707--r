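#' Describe one cohort variable
#'
#' A variable specification records how a column of a cohort file is typed and
#' used: its measurement kind, units, whether missing values are tolerated,
#' and its role (baseline predictor, follow-up predictor, or the continuous
#' target). Ordinal variables declare their grade range; continuous variables
#' may be flagged `skewed`, which switches the univariable group test from the
#' unpaired t-test to the Mann-Whitney U test.
#'
#' @param name Column name, unique within a schema.
#' @param kind One of `"continuous"`, `"binary"`, `"ordinal_grade"`,
#'   `"percentage"`.
#' @param units Free-text measurement units (may be `""`).
#' @param allow_missing Whether missing cells are permitted.
#' @param role One of `"baseline_predictor"`, `"followup_predictor"`,
#'   `"target"`.
#' @param skewed For continuous/percentage variables, whether the distribution
#'   is treated as skewed (median-based reporting, rank-based testing).
#' @param grade_min,grade_max Grade range for `ordinal_grade` variables.
#' @return A one-row data frame.
#' @export
variable_spec <- function(name, kind = "continuous", units = "",
                          allow_missing = TRUE, role = "baseline_predictor",
                          skewed = FALSE, grade_min = NA_real_,
                          grade_max = NA_real_) {
  kind <- match.arg(kind, c("continuous", "binary", "ordinal_grade", "percentage"))
  role <- match.arg(role, c("baseline_predictor", "followup_predictor", "target"))
  if (kind == "ordinal_grade" && (is.na(grade_min) || is.na(grade_max))) {
    stop("ordinal_grade variable '", name, "' must declare grade_min and grade_max")
  }
  data.frame(name = as.character(name), kind = kind, units = units,
             allow_missing = allow_missing, role = role, skewed = skewed,
             grade_min = grade_min, grade_max = grade_max,
             stringsAsFactors = FALSE)
}

#' Assemble and validate a cohort schema
#'
#' @param ... One-row data frames from [variable_spec()], or a single list of
#'   them.
#' @return A validated schema data frame (class `srg_schema`).
#' @export
make_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) && !is.data.frame(specs[[1]])) {
    specs <- specs[[1]]
  }
  schema <- do.call(rbind, specs)
  validate_schema(schema)
}

validate_schema <- function(schema) {
  if (anyDuplicated(schema$name)) {
    stop("schema variable names must be unique: ",
         paste(unique(schema$name[duplicated(schema$name)]), collapse = ", "))
  }
  n_target <- sum(schema$role == "target")
  if (n_target != 1L) {
    stop("schema must declare exactly one target variable (found ", n_target, ")")
  }
  bad <- schema$kind == "ordinal_grade" & (is.na(schema$grade_min) | is.na(schema$grade_max))
  if (any(bad)) {
    stop("ordinal_grade variables without a grade range: ",
         paste(schema$name[bad], collapse = ", "))
  }
  class(schema) <- c("srg_schema", "data.frame")
  schema
}

#' Read or write a schema as JSON
#'
#' @param path Path to a JSON file holding a list of variable entries (fields
#'   as in [variable_spec()]).
#' @return `read_schema()` returns a schema; `write_schema()` returns `path`
#'   invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  vars <- if (is.data.frame(raw)) raw else raw$variables
  defaults <- list(units = "", allow_missing = TRUE, role = "baseline_predictor",
                   skewed = FALSE, grade_min = NA_real_, grade_max = NA_real_)
  for (f in names(defaults)) {
    if (is.null(vars[[f]])) vars[[f]] <- defaults[[f]]
    vars[[f]][is.na(vars[[f]]) & !is.na(defaults[[f]])] <- defaults[[f]]
  }
  specs <- lapply(seq_len(nrow(vars)), function(i) {
    do.call(variable_spec, as.list(vars[i, c("name", "kind", "units",
                                             "allow_missing", "role", "skewed",
                                             "grade_min", "grade_max")]))
  })
  make_schema(specs)
}

#' @rdname read_schema
#' @param schema A schema data frame.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(list(variables = as.data.frame(schema)), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Infer a schema from a data frame
#'
#' Columns whose observed values are all in \{0, 1\} become `binary`; integer
#' columns with at most five distinct values in 0..4 become `ordinal_grade`;
#' everything else is `continuous`. The target column is matched by name.
#'
#' @param df A data frame of numeric columns.
#' @param target Name of the continuous target column.
#' @return A schema.
#' @export
infer_schema <- function(df, target = "MaxGD") {
  if (!target %in% names(df)) stop("target column '", target, "' not present")
  specs <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    v <- v[!is.na(v)]
    if (nm == target) {
      return(variable_spec(nm, "continuous", role = "target", allow_missing = FALSE))
    }
    if (length(v) && all(v %in% c(0, 1))) {
      return(variable_spec(nm, "binary"))
    }
    u <- unique(v)
    if (length(v) && all(v == round(v)) && length(u) <= 5 && all(u >= 0 & u <= 4)) {
      return(variable_spec(nm, "ordinal_grade", grade_min = min(u), grade_max = max(u)))
    }
    variable_spec(nm, "continuous")
  })
  make_schema(specs)
}
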