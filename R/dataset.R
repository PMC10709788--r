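#' Schema-validated tabular dataset
#'
#' Couples a data frame with a [tabular_schema()] and validates every cell
#' against it: categorical values must belong to the declared vocabulary,
#' numeric values must be finite, and no cell may be missing (records with
#' missing or unknown values are expected to be excluded upstream; this
#' container refuses them outright rather than imputing).
#'
#' @param data A data frame whose columns match the schema (order is taken
#'   from the schema).
#' @param schema A [tabular_schema()].
#' @return An object of class `tabular_dataset`: a list with elements
#'   `data` (data frame; categoricals stored as factors with the schema's
#'   levels) and `schema`.
#' @export
tabular_dataset <- function(data, schema) {
  stopifnot(inherits(schema, "tabular_schema"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(schema_colnames(schema), names(data))
  if (length(missing_cols)) {
    abort("data is missing schema column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(data), schema_colnames(schema))
  if (length(extra)) {
    abort("data has column(s) not declared in the schema: %s",
          paste(extra, collapse = ", "))
  }
  data <- data[schema_colnames(schema)]
  for (col in schema$columns) {
    x <- data[[col$name]]
    bad <- which(is.na(x) | (is.character(x) & !nzchar(trimws(x))))
    if (length(bad)) {
      abort("missing value in column '%s', row %d", col$name, bad[1L])
    }
    if (col$kind == "categorical") {
      x <- as.character(x)
      unknown <- which(!x %in% col$categories)
      if (length(unknown)) {
        abort("value '%s' in column '%s', row %d is not a declared category",
              x[unknown[1L]], col$name, unknown[1L])
      }
      data[[col$name]] <- factor(x, levels = col$categories)
    } else {
      if (is.character(x)) {
        xn <- suppressWarnings(as.numeric(x))
        bad <- which(is.na(xn))
        if (length(bad)) {
          abort("cannot parse '%s' in numeric column '%s', row %d",
                x[bad[1L]], col$name, bad[1L])
        }
        x <- xn
      }
      if (!is.numeric(x)) abort("column '%s' must be numeric", col$name)
      nf <- which(!is.finite(x))
      if (length(nf)) {
        abort("non-finite value in numeric column '%s', row %d",
              col$name, nf[1L])
      }
      data[[col$name]] <- as.numeric(x)
    }
  }
  rownames(data) <- NULL
  structure(list(data = data, schema = schema), class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset> %d rows x %d columns (target '%s')\n",
              nrow(x$data), ncol(x$data), x$schema$target))
  print(utils::head(x$data, 6L))
  if (nrow(x$data) > 6L) cat(sprintf("... %d more rows\n", nrow(x$data) - 6L))
  invisible(x)
}

#' @export
as.data.frame.tabular_dataset <- function(x, ...) x$data

#' Number of rows of a tabular dataset
#' @param ds A [tabular_dataset()].
#' @return Integer row count.
#' @export
n_rows <- function(ds) nrow(ds$data)

# internal: subset rows, preserving schema
dataset_slice <- function(ds, idx) {
  out <- ds
  out$data <- ds$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

# internal: rbind datasets sharing one schema
dataset_bind <- function(parts) {
  stopifnot(length(parts) >= 1L)
  ref <- parts[[1L]]$schema
  for (p in parts[-1L]) {
    if (!identical(schema_colnames(p$schema), schema_colnames(ref)) ||
        !identical(lapply(p$schema$columns, `[`, c("kind", "categories")),
                   lapply(ref$columns, `[`, c("kind", "categories")))) {
      abort("cannot combine datasets with different schemas")
    }
  }
  out <- parts[[1L]]
  out$data <- do.call(rbind, lapply(parts, `[[`, "data"))
  rownames(out$data) <- NULL
  out
}

# canonical character form of every row, for multiset comparisons in tests
dataset_row_keys <- function(ds) {
  df <- ds$data
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- format_numeric(df[[nm]])
    } else {
      df[[nm]] <- as.character(df[[nm]])
    }
  }
  do.call(paste, c(df, sep = "\x1f"))
}

# shortest round-trip decimal rendering (value-identical on re-read)
format_numeric <- function(x) {
  vapply(x, function(v) {
    for (d in c(1L, 7L, 15L, 16L, 17L)) {
      s <- format(v, digits = d, scientific = FALSE, trim = TRUE,
                  drop0trailing = TRUE)
      if (identical(as.numeric(s), as.numeric(v))) return(s)
    }
    s
  }, character(1))
}
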