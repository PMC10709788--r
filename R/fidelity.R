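# Fidelity metrics: per-column shape, per-pair trend, aggregates, and
# logical-consistency checking.

#' Kolmogorov-Smirnov statistic between two numeric columns
#'
#' Sup-distance between the two empirical CDFs, evaluated by a merge sweep
#' over the pooled values. 0 means identical distributions, 1 disjoint
#' supports.
#'
#' @param real,synthetic Non-empty numeric vectors.
#' @return KSS in `[0, 1]`.
#' @export
kss <- function(real, synthetic) {
  if (!length(real) || !length(synthetic)) abort("kss needs non-empty columns")
  pooled <- sort(unique(c(real, synthetic)))
  cdf_r <- ecdf_at(real, pooled)
  cdf_s <- ecdf_at(synthetic, pooled)
  max(abs(cdf_r - cdf_s))
}

ecdf_at <- function(x, points) {
  findInterval(points, sort(x)) / length(x)
}

#' Total variation distance between two categorical columns
#'
#' Half the L1 distance between the empirical probability mass functions,
#' taken over the union of observed categories. 0 means identical
#' frequencies, 1 disjoint supports.
#'
#' @param real,synthetic Non-empty categorical vectors (character/factor).
#' @return TVD in `[0, 1]`.
#' @export
tvd <- function(real, synthetic) {
  if (!length(real) || !length(synthetic)) abort("tvd needs non-empty columns")
  real <- as.character(real)
  synthetic <- as.character(synthetic)
  cats <- union(real, synthetic)
  p <- as.numeric(table(factor(real, levels = cats))) / length(real)
  q <- as.numeric(table(factor(synthetic, levels = cats))) / length(synthetic)
  sum(abs(p - q)) / 2
}

#' Correlation similarity for a numeric column pair
#'
#' Compares the Pearson correlation of a column pair in the real data with
#' the same pair in the synthetic data:
#' `1 - |rho_real - rho_synthetic| / 2`, bounded in `[0, 1]` (the
#' correlations themselves span `[-1, 1]`, so their gap spans `[0, 2]`).
#'
#' @param real_x,real_y Numeric columns from the real data.
#' @param syn_x,syn_y The same columns from the synthetic data.
#' @return Similarity in `[0, 1]`.
#' @export
correlation_similarity <- function(real_x, real_y, syn_x, syn_y) {
  rho_r <- suppressWarnings(stats::cor(real_x, real_y))
  rho_s <- suppressWarnings(stats::cor(syn_x, syn_y))
  if (!is.finite(rho_r) || !is.finite(rho_s)) {
    abort("correlation undefined (constant column); use the contingency path")
  }
  min(max(1 - abs(rho_r - rho_s) / 2, 0), 1)
}

#' Contingency similarity for a categorical column pair
#'
#' Compares the joint category proportions (cross-tabulations, normalized
#' to proportions) of a column pair between real and synthetic data:
#' `1 - 0.5 * sum(|P_real(cell) - P_syn(cell)|)` over the union of observed
#' category combinations.
#'
#' @param real_x,real_y Categorical columns from the real data.
#' @param syn_x,syn_y The same columns from the synthetic data.
#' @return Similarity in `[0, 1]`.
#' @export
contingency_similarity <- function(real_x, real_y, syn_x, syn_y) {
  if (!length(real_x) || !length(syn_x)) {
    abort("contingency_similarity needs non-empty columns")
  }
  key_r <- paste(as.character(real_x), as.character(real_y), sep = "\x1f")
  key_s <- paste(as.character(syn_x), as.character(syn_y), sep = "\x1f")
  cells <- union(key_r, key_s)
  p <- as.numeric(table(factor(key_r, levels = cells))) / length(key_r)
  q <- as.numeric(table(factor(key_s, levels = cells))) / length(key_s)
  1 - sum(abs(p - q)) / 2
}

#' Full fidelity report between real and synthetic data
#'
#' Per-column *shape* scores (1 − KSS for numeric, 1 − TVD for categorical),
#' per-pair *trend* scores (correlation similarity for numeric-numeric
#' pairs; contingency similarity otherwise, with any numeric member
#' discretized using bins fitted on the real data and applied to both), and
#' three aggregates: `shape` (mean column score), `pair_trend` (mean pair
#' score) and `overall` (mean of the two). All scores lie in `[0, 1]`;
#' identical inputs score exactly 1. Reported tables conventionally show
#' these x 100.
#'
#' @param real,synthetic Two [tabular_dataset()] objects with one schema.
#' @param n_bins Bins for discretizing numeric members of mixed pairs.
#' @return An object of class `fidelity_report`.
#' @export
quality_report <- function(real, synthetic, n_bins = 10L) {
  stopifnot(inherits(real, "tabular_dataset"),
            inherits(synthetic, "tabular_dataset"))
  if (!identical(schema_colnames(real$schema),
                 schema_colnames(synthetic$schema))) {
    abort("real and synthetic datasets must share one schema")
  }
  cols <- schema_colnames(real$schema)
  numeric_cols <- cols[vapply(cols, function(cn)
    schema_kind(real$schema, cn) == "numeric", logical(1))]

  column_scores <- vapply(cols, function(cn) {
    if (cn %in% numeric_cols) {
      1 - kss(real$data[[cn]], synthetic$data[[cn]])
    } else {
      1 - tvd(real$data[[cn]], synthetic$data[[cn]])
    }
  }, numeric(1))

  # categorical views of every column, bins fitted on real data
  cat_real <- list()
  cat_syn <- list()
  for (cn in cols) {
    if (cn %in% numeric_cols) {
      bins <- fit_bins(real$data[[cn]], n_bins)
      cat_real[[cn]] <- as.character(apply_bins(bins, real$data[[cn]]))
      cat_syn[[cn]] <- as.character(apply_bins(bins, synthetic$data[[cn]]))
    } else {
      cat_real[[cn]] <- as.character(real$data[[cn]])
      cat_syn[[cn]] <- as.character(synthetic$data[[cn]])
    }
  }

  pair_scores <- numeric(0)
  if (length(cols) >= 2) {
    for (i in seq_len(length(cols) - 1)) {
      for (j in seq(i + 1, length(cols))) {
        a <- cols[i]; b <- cols[j]
        both_numeric <- a %in% numeric_cols && b %in% numeric_cols
        constant <- both_numeric &&
          (stats::sd(real$data[[a]]) == 0 || stats::sd(real$data[[b]]) == 0 ||
           stats::sd(synthetic$data[[a]]) == 0 ||
           stats::sd(synthetic$data[[b]]) == 0)
        score <- if (both_numeric && !constant) {
          correlation_similarity(real$data[[a]], real$data[[b]],
                                 synthetic$data[[a]], synthetic$data[[b]])
        } else {
          contingency_similarity(cat_real[[a]], cat_real[[b]],
                                 cat_syn[[a]], cat_syn[[b]])
        }
        pair_scores[paste(a, b, sep = ":")] <- score
      }
    }
  }

  shape <- mean(column_scores)
  pair_trend <- if (length(pair_scores)) mean(pair_scores) else NA_real_
  overall <- if (is.na(pair_trend)) shape else mean(c(shape, pair_trend))
  structure(list(column_scores = column_scores, pair_scores = pair_scores,
                 shape = shape, pair_trend = pair_trend, overall = overall),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, digits = 2, ...) {
  cat("<fidelity_report> (scores x 100)\n")
  cat(sprintf("  shape:      %.*f\n", digits, 100 * x$shape))
  cat(sprintf("  pair trend: %.*f\n", digits, 100 * x$pair_trend))
  cat(sprintf("  overall:    %.*f\n", digits, 100 * x$overall))
  invisible(x)
}

#' Logical-rule violation report
#'
#' Counts, per rule and overall, the rows whose trigger column matches the
#' rule's trigger value while the dependent column deviates from the
#' required constant (numeric equality within absolute tolerance `1e-9`).
#' These are the "impossible records" — e.g. a non-smoker with positive
#' pack-years — that make synthetic data unusable for downstream analyses.
#'
#' @param ds A [tabular_dataset()].
#' @param rules List of [logical_rule()] objects (default: schema rules).
#' @return An object of class `violation_report`: list with `n_rows`,
#'   `violations_per_rule` (named counts) and `violation_rate` (fraction of
#'   rows breaking at least one rule).
#' @export
violation_report <- function(ds, rules = ds$schema$rules) {
  stopifnot(inherits(ds, "tabular_dataset"))
  per_rule <- integer(length(rules))
  names(per_rule) <- vapply(rules, format, character(1))
  any_viol <- rep(FALSE, n_rows(ds))
  for (k in seq_along(rules)) {
    v <- row_violates(ds, rules[k])
    per_rule[k] <- sum(v)
    any_viol <- any_viol | v
  }
  structure(list(n_rows = n_rows(ds), violations_per_rule = per_rule,
                 violation_rate = if (n_rows(ds)) mean(any_viol) else 0),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf("<violation_report> %d rows, violation rate %.4f\n",
              x$n_rows, x$violation_rate))
  for (nm in names(x$violations_per_rule)) {
    cat(sprintf("  %-50s %d\n", nm, x$violations_per_rule[[nm]]))
  }
  invisible(x)
}
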