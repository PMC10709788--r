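# CSV + JSON schema-sidecar input/output.

#' Read a schema sidecar
#'
#' The sidecar is a JSON document
#' `{"columns": [{"name", "kind", "categories?", "role"}], "target": name,
#'   "rules": [{"trigger_column", "trigger_value", "dependent_column",
#'   "required_value"}]}`.
#'
#' @param path Path to the JSON sidecar.
#' @return A [tabular_schema()].
#' @export
read_schema <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$columns)) abort("schema sidecar has no 'columns' entry")
  cols <- lapply(doc$columns, function(cc) {
    col_schema(name = cc$name, kind = cc$kind,
               categories = if (!is.null(cc$categories))
                 unlist(cc$categories, use.names = FALSE),
               role = if (is.null(cc$role)) "feature" else cc$role)
  })
  rules <- lapply(doc$rules %||% list(), function(r) {
    logical_rule(r$trigger_column, r$trigger_value,
                 r$dependent_column, r$required_value)
  })
  tabular_schema(cols, target = doc$target, rules = rules)
}

#' Write a schema sidecar
#'
#' @param schema A [tabular_schema()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_schema <- function(schema, path) {
  doc <- list(
    columns = unname(lapply(schema$columns, function(col) {
      out <- list(name = col$name, kind = col$kind, role = col$role)
      if (!is.null(col$categories)) out$categories <- as.list(col$categories)
      out
    })),
    target = schema$target,
    rules = unname(lapply(schema$rules, function(r) {
      list(trigger_column = r$trigger_column,
           trigger_value = r$trigger_value,
           dependent_column = r$dependent_column,
           required_value = r$required_value)
    }))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a CSV table against a schema sidecar
#'
#' Loads an RFC-4180-style CSV with a header row and validates it against
#' the sidecar. Any missing cell, undeclared category or unparsable numeric
#' aborts the load with the offending row and column named; records with
#' missing or unknown values must be handled before modelling, not silently
#' patched here.
#'
#' @param csv_path Path to the CSV file.
#' @param schema_path Path to the JSON sidecar, or a [tabular_schema()].
#' @return A [tabular_dataset()], row order preserved.
#' @export
read_dataset <- function(csv_path, schema_path) {
  schema <- if (inherits(schema_path, "tabular_schema")) schema_path
            else read_schema(schema_path)
  df <- utils::read.csv(csv_path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  undeclared <- setdiff(names(df), schema_colnames(schema))
  if (length(undeclared)) {
    abort("CSV column(s) not declared in schema: %s",
          paste(undeclared, collapse = ", "))
  }
  tabular_dataset(df, schema)
}

#' Write a dataset to CSV
#'
#' Numerics are rendered in the shortest decimal form that reads back to
#' the identical double, so `read_dataset(write_dataset(d))` equals `d`.
#'
#' @param ds A [tabular_dataset()].
#' @param csv_path Output path.
#' @return Invisibly, `csv_path`.
#' @export
write_dataset <- function(ds, csv_path) {
  stopifnot(inherits(ds, "tabular_dataset"))
  df <- ds$data
  for (nm in names(df)) {
    df[[nm]] <- if (is.numeric(df[[nm]])) format_numeric(df[[nm]])
                else as.character(df[[nm]])
  }
  utils::write.csv(df, csv_path, row.names = FALSE, quote = TRUE)
  invisible(csv_path)
}
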