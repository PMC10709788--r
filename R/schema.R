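#' Column schema entry
#'
#' Declares one column of a tabular clinical dataset: its name, whether it is
#' categorical or numeric, its category vocabulary (categorical only) and its
#' role (ordinary feature or the binary outcome).
#'
#' @param name Column name (non-empty string).
#' @param kind `"categorical"` or `"numeric"`.
#' @param categories Character vector of allowed category labels, in order.
#'   Required for categorical columns; must be `NULL` for numeric columns.
#'   For the target column the second listed category is treated as the
#'   positive/event class (death, recurrence, readmission, ...).
#' @param role `"feature"` or `"target"`.
#' @return An object of class `col_schema`.
#' @export
#' @examples
#' col_schema("smoker", "categorical", c("no", "yes"))
#' col_schema("age", "numeric")
col_schema <- function(name, kind = c("categorical", "numeric"),
                       categories = NULL, role = c("feature", "target")) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("column name must be a non-empty string")
  }
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) == 0L) {
      abort("categorical column '%s' needs a non-empty category list", name)
    }
    categories <- as.character(categories)
    if (anyDuplicated(categories)) {
      abort("categories of column '%s' contain duplicates", name)
    }
  } else {
    if (!is.null(categories)) {
      abort("numeric column '%s' must not declare categories", name)
    }
  }
  if (role == "target") {
    if (kind != "categorical" || length(categories) != 2L) {
      abort("target column '%s' must be categorical with exactly 2 categories",
            name)
    }
  }
  structure(list(name = name, kind = kind, categories = categories,
                 role = role),
            class = "col_schema")
}

#' Logical rule linking a main attribute to its subattribute
#'
#' Encodes a deterministic "trigger implies constant" constraint: whenever
#' `trigger_column == trigger_value`, `dependent_column` must equal
#' `required_value` (e.g. smoker == "no" implies pack_years == 0). Rows
#' breaking such a rule are the "impossible records" that naive generators
#' produce.
#'
#' @param trigger_column Name of the (categorical) trigger column.
#' @param trigger_value Category label that arms the rule.
#' @param dependent_column Name of the constrained column.
#' @param required_value Constant (category label or numeric) the dependent
#'   column must take when the rule is armed.
#' @return An object of class `logical_rule`.
#' @export
#' @examples
#' logical_rule("smoker", "no", "pack_years", 0)
logical_rule <- function(trigger_column, trigger_value,
                         dependent_column, required_value) {
  if (identical(trigger_column, dependent_column)) {
    abort("a rule cannot constrain its own trigger column")
  }
  structure(list(trigger_column = trigger_column,
                 trigger_value = as.character(trigger_value),
                 dependent_column = dependent_column,
                 required_value = required_value),
            class = "logical_rule")
}

#' @export
format.logical_rule <- function(x, ...) {
  sprintf("if %s == \"%s\" then %s == %s",
          x$trigger_column, x$trigger_value, x$dependent_column,
          if (is.character(x$required_value))
            sprintf("\"%s\"", x$required_value)
          else format(x$required_value))
}

#' @export
print.logical_rule <- function(x, ...) {
  cat("<logical_rule> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Table schema
#'
#' Bundles the column declarations, the binary target column and any logical
#' rules into a validated schema object.
#'
#' @param columns List of [col_schema()] objects.
#' @param target Name of the target column. Defaults to the single column
#'   declared with role `"target"`.
#' @param rules List of [logical_rule()] objects.
#' @return An object of class `tabular_schema`.
#' @export
tabular_schema <- function(columns, target = NULL, rules = list()) {
  if (!length(columns)) abort("a schema needs at least one column")
  if (!all(vapply(columns, inherits, logical(1), "col_schema"))) {
    abort("every element of 'columns' must be a col_schema")
  }
  names(columns) <- vapply(columns, `[[`, character(1), "name")
  if (anyDuplicated(names(columns))) {
    abort("duplicate column names in schema: %s",
          paste(unique(names(columns)[duplicated(names(columns))]),
                collapse = ", "))
  }
  roles <- vapply(columns, `[[`, character(1), "role")
  declared_target <- names(columns)[roles == "target"]
  if (is.null(target)) {
    if (length(declared_target) != 1L) {
      abort("schema must declare exactly one target column (found %d)",
            length(declared_target))
    }
    target <- declared_target
  } else {
    if (!target %in% names(columns)) {
      abort("target column '%s' is not declared in the schema", target)
    }
    columns[[target]]$role <- "target"
    tc <- columns[[target]]
    if (tc$kind != "categorical" || length(tc$categories) != 2L) {
      abort("target column '%s' must be categorical with exactly 2 categories",
            target)
    }
    for (other in setdiff(names(columns)[roles == "target"], target)) {
      columns[[other]]$role <- "feature"
    }
  }
  rules <- lapply(rules, function(r) {
    if (!inherits(r, "logical_rule")) abort("rules must be logical_rule objects")
    for (cn in c(r$trigger_column, r$dependent_column)) {
      if (!cn %in% names(columns)) {
        abort("rule references unknown column '%s'", cn)
      }
    }
    tcol <- columns[[r$trigger_column]]
    if (tcol$kind != "categorical") {
      abort("rule trigger column '%s' must be categorical", r$trigger_column)
    }
    if (!r$trigger_value %in% tcol$categories) {
      abort("rule trigger value '%s' is not a category of '%s'",
            r$trigger_value, r$trigger_column)
    }
    r
  })
  structure(list(columns = columns, target = target, rules = rules),
            class = "tabular_schema")
}

#' @export
print.tabular_schema <- function(x, ...) {
  cat(sprintf("<tabular_schema> %d columns, target '%s', %d rule(s)\n",
              length(x$columns), x$target, length(x$rules)))
  for (col in x$columns) {
    cat(sprintf("  %-16s %-11s %s%s\n", col$name, col$kind,
                if (col$kind == "categorical")
                  paste0("{", paste(col$categories, collapse = ", "), "}")
                else "",
                if (col$role == "target") "  [target]" else ""))
  }
  for (r in x$rules) cat("  rule: ", format(r), "\n", sep = "")
  invisible(x)
}

# convenience accessors ------------------------------------------------------

schema_colnames <- function(schema) names(schema$columns)

schema_kind <- function(schema, col) schema$columns[[col]]$kind

schema_feature_names <- function(schema) {
  setdiff(names(schema$columns), schema$target)
}

#' Positive (event) class label of a schema's target
#'
#' By convention the second listed category of the target column is the
#' event class; `event_level` lets callers override that convention.
#'
#' @param schema A [tabular_schema()].
#' @param event_level Optional explicit category label.
#' @return A category label.
#' @export
target_event_class <- function(schema, event_level = NULL) {
  cats <- schema$columns[[schema$target]]$categories
  if (is.null(event_level)) return(cats[2L])
  if (!event_level %in% cats) {
    abort("event level '%s' is not a category of target '%s'",
          event_level, schema$target)
  }
  event_level
}
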