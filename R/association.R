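# Chi-square / Cramer V association analysis and division-pair detection.

#' Contingency table for two categorical columns
#'
#' Cross-tabulates two categorical (or pre-discretized) columns of a
#' dataset. Categories with zero marginal count are dropped before the row
#' and column counts are fixed, so a sparse vocabulary never inflates the
#' table's degrees of freedom.
#'
#' @param ds A [tabular_dataset()].
#' @param col_a,col_b Column names; both must be categorical.
#' @return An object of class `contingency_table`: list with `counts`
#'   (r x c integer matrix), `N`, `r`, `c` and `chi2` (Pearson chi-square,
#'   no continuity correction).
#' @export
contingency_table <- function(ds, col_a, col_b) {
  stopifnot(inherits(ds, "tabular_dataset"))
  for (cn in c(col_a, col_b)) {
    if (!cn %in% schema_colnames(ds$schema)) {
      abort("unknown column '%s'", cn)
    }
    if (schema_kind(ds$schema, cn) != "categorical") {
      abort("column '%s' is numeric; discretize it first", cn)
    }
  }
  tab <- table(as.character(ds$data[[col_a]]), as.character(ds$data[[col_b]]))
  new_contingency_table(unclass(tab))
}

# build from a plain counts matrix, dropping empty rows/columns
new_contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  N <- sum(counts)
  chi2 <- if (nrow(counts) >= 1 && ncol(counts) >= 1 && N > 0)
    pearson_chi2(counts) else 0
  structure(list(counts = counts, N = N,
                 r = nrow(counts), c = ncol(counts), chi2 = chi2),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %d x %d, N = %d, chi2 = %.6g\n",
              x$r, x$c, x$N, x$chi2))
  print(x$counts)
  invisible(x)
}

pearson_chi2 <- function(counts) {
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - expected)^2 / expected)
}

#' Pearson chi-square statistic of a contingency table
#'
#' Classical `sum((O - E)^2 / E)` over all cells, with expected counts from
#' the product of the marginals. No Yates continuity correction is applied.
#'
#' @param tab A `contingency_table` or a plain counts matrix.
#' @return Nonnegative chi-square statistic.
#' @export
chi_square_statistic <- function(tab) {
  if (!inherits(tab, "contingency_table")) tab <- new_contingency_table(tab)
  if (tab$N == 0) abort("empty contingency table")
  if (any(rowSums(tab$counts) == 0) || any(colSums(tab$counts) == 0)) {
    abort("zero marginal in contingency table; drop empty categories first")
  }
  tab$chi2
}

#' Cramer V association coefficient
#'
#' `V = sqrt(chi2 / (N * min(r - 1, c - 1)))`, where `chi2` is the Pearson
#' chi-square of the table, `N` the number of observations and `r`, `c` the
#' table dimensions after empty categories are dropped. V ranges from 0
#' (independence) to 1 (complete association). A table with a single
#' observed row or column carries no measurable association and scores 0.
#' No small-sample bias correction is applied.
#'
#' @param tab A `contingency_table` or a plain counts matrix.
#' @return V in `[0, 1]` (clamped against floating-point overshoot).
#' @export
#' @examples
#' cramers_v(matrix(c(10, 0, 0, 10), 2))        # 1: perfect association
#' cramers_v(matrix(c(5, 5, 5, 5), 2))          # 0: independence
#' cramers_v(matrix(c(20, 5, 5, 20), 2))        # 0.6
cramers_v <- function(tab) {
  if (!inherits(tab, "contingency_table")) tab <- new_contingency_table(tab)
  if (tab$r < 2 || tab$c < 2) return(0)
  v <- sqrt(tab$chi2 / (tab$N * min(tab$r - 1, tab$c - 1)))
  min(max(v, 0), 1)
}

#' Equal-frequency discretization with a point-mass carve-out
#'
#' Converts a numeric column to categorical for association analysis.
#' Any single value occurring in at least `1/n_bins` of the rows (a point
#' mass, typically a structural zero such as the pack-years of non-smokers)
#' receives its own dedicated bin; the remaining values are quantile-binned
#' into the remaining bins with duplicate edges collapsed. Without the
#' carve-out a structural zero is smeared across a quantile bin and a
#' perfect main-attribute/subattribute association is invisible to Cramer V.
#'
#' @param x Numeric vector.
#' @param n_bins Total number of bins (>= 2); default 10.
#' @return Factor with point-mass labels (the value itself) and interval
#'   labels. A constant column collapses to a single bin.
#' @export
discretize_numeric <- function(x, n_bins = 10L) {
  if (!is_count(n_bins, min = 2L)) abort("n_bins must be an integer >= 2")
  x <- as.numeric(x)
  if (!length(x)) abort("cannot discretize an empty column")
  bins <- fit_bins(x, n_bins)
  apply_bins(bins, x)
}

# fit binning on (real) data so the same edges can be applied to synthetic
fit_bins <- function(x, n_bins = 10L) {
  n <- length(x)
  tabx <- table(x)
  point_masses <- as.numeric(names(tabx))[tabx / n >= 1 / n_bins]
  rest <- x[!x %in% point_masses]
  n_rest_bins <- max(n_bins - length(point_masses), 1L)
  if (length(rest) == 0L || length(unique(rest)) == 1L) {
    breaks <- if (length(rest)) range(rest) else numeric(0)
  } else {
    qs <- stats::quantile(rest, probs = seq(0, 1, length.out = n_rest_bins + 1),
                          type = 7, names = FALSE)
    breaks <- unique(qs)
  }
  list(point_masses = sort(point_masses), breaks = breaks)
}

apply_bins <- function(bins, x) {
  x <- as.numeric(x)
  pm <- bins$point_masses
  labels_pm <- format_numeric(pm)
  out <- character(length(x))
  is_pm <- x %in% pm
  if (any(is_pm)) {
    out[is_pm] <- labels_pm[match(x[is_pm], pm)]
  }
  rest_idx <- which(!is_pm)
  br <- bins$breaks
  if (length(rest_idx)) {
    if (length(br) < 2) {
      # no interval structure fitted: single catch-all bin
      out[rest_idx] <- "(rest)"
      labels_int <- "(rest)"
    } else {
      # clamp out-of-range values into the edge bins
      cutx <- pmin(pmax(x[rest_idx], br[1]), br[length(br)])
      f <- cut(cutx, breaks = br, include.lowest = TRUE)
      out[rest_idx] <- as.character(f)
      labels_int <- levels(f)
    }
  } else {
    labels_int <- character(0)
  }
  factor(out, levels = c(labels_pm, labels_int))
}

#' Cramer V matrix over all column pairs
#'
#' Discretizes numeric columns via [discretize_numeric()], then computes
#' pairwise Cramer V for every unordered column pair. The diagonal is fixed
#' at 1.
#'
#' @param ds A [tabular_dataset()].
#' @param n_bins Bins used to discretize numeric columns (default 10).
#' @return An object of class `association_matrix`: a symmetric numeric
#'   matrix with unit diagonal and dimnames equal to the column names.
#' @export
cramers_v_matrix <- function(ds, n_bins = 10L) {
  stopifnot(inherits(ds, "tabular_dataset"))
  cols <- schema_colnames(ds$schema)
  cat_cols <- lapply(cols, function(cn) {
    if (schema_kind(ds$schema, cn) == "numeric")
      as.character(discretize_numeric(ds$data[[cn]], n_bins))
    else
      as.character(ds$data[[cn]])
  })
  names(cat_cols) <- cols
  p <- length(cols)
  V <- diag(1, p)
  dimnames(V) <- list(cols, cols)
  if (p >= 2) {
    for (i in seq_len(p - 1)) {
      for (j in seq(i + 1, p)) {
        tab <- new_contingency_table(table(cat_cols[[i]], cat_cols[[j]]))
        V[i, j] <- V[j, i] <- cramers_v(tab)
      }
    }
  }
  structure(V, class = c("association_matrix", "matrix"))
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("<association_matrix> Cramer V over all column pairs\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Find division-candidate column pairs
#'
#' Returns every unordered pair of feature columns whose Cramer V reaches
#' the threshold (default 1, within an absolute tolerance for floating
#' point). Pairs involving the target column are excluded: the class split
#' is always applied separately. The result is sorted by descending V then
#' lexicographically.
#'
#' @param vmat An `association_matrix` from [cramers_v_matrix()].
#' @param threshold Detection threshold in `(0, 1]`; default 1.
#' @param target Name of the target column to exclude (optional; pairs with
#'   this column are dropped).
#' @param tol Absolute tolerance below the threshold; default `1e-9`.
#' @return Data frame with columns `col_a`, `col_b`, `v` (possibly 0 rows).
#' @export
find_division_pairs <- function(vmat, threshold = 1, target = NULL,
                                tol = 1e-9) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort("threshold must lie in (0, 1]")
  }
  cols <- rownames(vmat)
  out <- list()
  if (length(cols) >= 2) {
    for (i in seq_len(length(cols) - 1)) {
      for (j in seq(i + 1, length(cols))) {
        if (!is.null(target) && (cols[i] == target || cols[j] == target)) next
        if (vmat[i, j] >= threshold - tol) {
          pair <- sort(c(cols[i], cols[j]))
          out[[length(out) + 1L]] <- data.frame(
            col_a = pair[1], col_b = pair[2], v = vmat[i, j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(col_a = character(0), col_b = character(0),
                      v = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(-res$v, res$col_a, res$col_b), , drop = FALSE]
}
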