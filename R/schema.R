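#' Describe a single variable
#'
#' A variable schema records everything the synthesis engine needs to know
#' about one column: its name, its measurement kind and, for categorical
#' variables, the ordered set of category labels. Missing values are always
#' represented by `NA` regardless of the source encoding (Stata extended
#' missing codes collapse to `NA` on import).
#'
#' @param name Column name (non-empty string, unique within a table schema).
#' @param kind One of `"continuous"`, `"binary"`, `"nominal"`, `"ordinal"`.
#' @param levels Character vector of category labels, in order. Must be empty
#'   for continuous variables, non-empty (and duplicate-free) otherwise;
#'   binary variables must have exactly two levels.
#' @param missing_allowed Logical; whether `NA` is a legal value.
#'
#' @return An object of class `variable_schema`.
#' @seealso [table_schema()]
#' @export
variable_schema <- function(name, kind, levels = character(), missing_allowed = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kind <- match.arg(kind, c("continuous", "binary", "nominal", "ordinal"))
  levels <- as.character(levels)
  if (kind == "continuous" && length(levels) > 0L)
    stop("continuous variable '", name, "' must not declare levels")
  if (kind != "continuous") {
    if (length(levels) == 0L)
      stop("categorical variable '", name, "' needs at least one level")
    if (anyDuplicated(levels))
      stop("duplicate levels in schema for '", name, "'")
    if (kind == "binary" && length(levels) != 2L)
      stop("binary variable '", name, "' must have exactly 2 levels")
  }
  structure(
    list(name = name, kind = kind, levels = levels,
         missing_allowed = isTRUE(missing_allowed)),
    class = "variable_schema"
  )
}

#' @export
print.variable_schema <- function(x, ...) {
  cat(sprintf("<variable_schema> %s: %s", x$name, x$kind))
  if (length(x$levels)) cat(" {", paste(x$levels, collapse = ", "), "}")
  cat(if (x$missing_allowed) " [NA ok]\n" else "\n")
  invisible(x)
}

#' Infer or assemble the schema of a rectangular table
#'
#' When given a data frame, the schema is inferred: factor/character columns
#' become categorical (two observed levels => binary, ordered factors =>
#' ordinal, otherwise nominal) and numeric columns become continuous. When
#' given a list of [variable_schema()] objects it validates and wraps them.
#'
#' @param x A data frame, or a list of `variable_schema` objects.
#' @param overrides Optional named list mapping column names to
#'   `variable_schema` objects that replace the inferred entry (e.g. to force
#'   an integer score to be treated as continuous, or to declare unobserved
#'   levels).
#'
#' @return An object of class `table_schema`: a named list of
#'   `variable_schema` entries in column order.
#' @export
table_schema <- function(x, overrides = list()) {
  if (is.data.frame(x)) {
    if (ncol(x) == 0L) stop("cannot infer a schema from a zero-column table")
    entries <- lapply(names(x), function(nm) infer_variable_schema(x[[nm]], nm))
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "variable_schema"))) {
    entries <- x
  } else {
    stop("x must be a data frame or a list of variable_schema objects")
  }
  names(entries) <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(names(entries)))
    stop("duplicate variable names in schema: ",
         paste(unique(names(entries)[duplicated(names(entries))]), collapse = ", "))
  for (nm in names(overrides)) {
    if (!inherits(overrides[[nm]], "variable_schema"))
      stop("override for '", nm, "' is not a variable_schema")
    entries[[nm]] <- overrides[[nm]]
  }
  structure(entries, class = "table_schema")
}

infer_variable_schema <- function(col, nm) {
  if (is.factor(col)) {
    kind <- if (is.ordered(col)) "ordinal" else
      if (nlevels(col) == 2L) "binary" else "nominal"
    variable_schema(nm, kind, levels(col), anyNA(col))
  } else if (is.character(col)) {
    lev <- sort(unique(col[!is.na(col)]))
    kind <- if (length(lev) == 2L) "binary" else "nominal"
    variable_schema(nm, kind, lev, anyNA(col))
  } else if (is.logical(col)) {
    variable_schema(nm, "binary", c("FALSE", "TRUE"), anyNA(col))
  } else if (is.numeric(col)) {
    variable_schema(nm, "continuous", character(), anyNA(col))
  } else {
    stop("cannot infer schema for column '", nm, "' of class ",
         paste(class(col), collapse = "/"))
  }
}

#' @export
print.table_schema <- function(x, ...) {
  cat("<table_schema> ", length(x), " variables\n", sep = "")
  for (v in x) {
    cat(sprintf("  %-14s %-10s", v$name, v$kind))
    if (length(v$levels)) cat(" (", length(v$levels), " levels)", sep = "")
    cat("\n")
  }
  invisible(x)
}

schema_kind <- function(schema, name) schema[[name]]$kind

is_categorical_kind <- function(kind) kind %in% c("binary", "nominal", "ordinal")

#' Coerce a data frame to match a table schema
#'
#' Categorical columns become factors over the schema's level set (values
#' outside the level set become `NA`); continuous columns become numeric.
#' Column order follows the schema.
#'
#' @param data A data frame.
#' @param schema A [table_schema()].
#' @return A data frame conforming to the schema.
#' @export
conform_to_schema <- function(data, schema) {
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols))
    stop("data lacks schema columns: ", paste(missing_cols, collapse = ", "))
  out <- data[names(schema)]
  for (v in schema) {
    if (is_categorical_kind(v$kind)) {
      out[[v$name]] <- factor(as.character(out[[v$name]]), levels = v$levels,
                              ordered = v$kind == "ordinal")
    } else {
      out[[v$name]] <- as.numeric(out[[v$name]])
    }
  }
  out
}
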