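# The "divide" step: class-specific split, then splits on division features.

#' Pick the main attribute of a perfectly associated pair
#'
#' A V = 1 pair links a main attribute (e.g. smoking status) to its
#' subattribute (e.g. pack-years). The member with fewer observed
#' categories is taken as the division feature; ties break toward the
#' natively categorical member, then lexicographically.
#'
#' @param ds A [tabular_dataset()].
#' @param pair Character vector of two column names (a row of
#'   [find_division_pairs()] output also works).
#' @param n_bins Bins used when counting categories of a numeric member.
#' @return A single column name.
#' @export
derive_division_feature <- function(ds, pair, n_bins = 10L) {
  if (is.data.frame(pair)) pair <- c(pair$col_a[1], pair$col_b[1])
  stopifnot(length(pair) == 2L)
  n_cats <- vapply(pair, function(cn) {
    if (schema_kind(ds$schema, cn) == "categorical")
      length(unique(as.character(ds$data[[cn]])))
    else
      length(unique(as.character(discretize_numeric(ds$data[[cn]], n_bins))))
  }, numeric(1))
  native <- vapply(pair, function(cn)
    schema_kind(ds$schema, cn) == "categorical", logical(1))
  ord <- order(n_cats, !native, pair)
  pair[ord[1L]]
}

#' Division criteria
#'
#' Bundles the target column with the ordered division features derived
#' from V = 1 pairs.
#'
#' @param ds A [tabular_dataset()].
#' @param pairs Data frame from [find_division_pairs()] (may have 0 rows).
#' @param n_bins Bins forwarded to [derive_division_feature()].
#' @return An object of class `division_criteria`.
#' @export
division_criteria <- function(ds, pairs, n_bins = 10L) {
  feats <- character(0)
  derivations <- list()
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      f <- derive_division_feature(ds, pairs[k, ], n_bins)
      if (f %in% feats || f == ds$schema$target) next
      if (schema_kind(ds$schema, f) != "categorical") next
      feats <- c(feats, f)
      derivations[[f]] <- c(pairs$col_a[k], pairs$col_b[k])
    }
  }
  structure(list(target_column = ds$schema$target,
                 division_features = feats,
                 derivations = derivations),
            class = "division_criteria")
}

#' @export
print.division_criteria <- function(x, ...) {
  cat(sprintf("<division_criteria> target '%s'; %d division feature(s)%s\n",
              x$target_column, length(x$division_features),
              if (length(x$division_features))
                paste0(": ", paste(x$division_features, collapse = ", "))
              else ""))
  invisible(x)
}

#' Build the class-by-feature cross partition
#'
#' Splits the dataset by target class first, then by each division feature
#' in order, giving e.g. the four death-smoker / death-nonsmoker /
#' survival-smoker / survival-nonsmoker subsets. If a split would leave any
#' resulting subset under `min_subset_size` rows, the most recently applied
#' division feature is dropped for that class branch (over-division starves
#' the per-subset generators of training data); the class split itself
#' always survives.
#'
#' @param ds A [tabular_dataset()].
#' @param criteria A [division_criteria()].
#' @param min_subset_size Smallest admissible subset (default 50).
#' @return An object of class `dc_partition`: list of subsets, each with a
#'   `label` (named list column -> value) and `data` ([tabular_dataset()]).
#' @export
build_partition <- function(ds, criteria, min_subset_size = 50L) {
  stopifnot(inherits(ds, "tabular_dataset"),
            inherits(criteria, "division_criteria"))
  if (!is_count(min_subset_size, min = 1L)) {
    abort("min_subset_size must be a positive integer")
  }
  target <- criteria$target_column
  classes <- ds$schema$columns[[target]]$categories
  cls_vec <- as.character(ds$data[[target]])
  for (cl in classes) {
    if (!any(cls_vec == cl)) {
      abort("target class '%s' has no rows; cannot class-split", cl)
    }
  }
  subsets <- list()
  dropped <- character(0)
  for (cl in classes) {
    branch <- list(list(label = stats::setNames(list(cl), target),
                        idx = which(cls_vec == cl)))
    for (feat in criteria$division_features) {
      fv <- as.character(ds$data[[feat]])
      proposal <- list()
      for (b in branch) {
        vals <- unique(fv[b$idx])
        for (v in sort(vals)) {
          lab <- b$label
          lab[[feat]] <- v
          proposal[[length(proposal) + 1L]] <-
            list(label = lab, idx = b$idx[fv[b$idx] == v])
        }
      }
      sizes <- vapply(proposal, function(p) length(p$idx), numeric(1))
      if (any(sizes < min_subset_size)) {
        dropped <- c(dropped, sprintf(
          "class '%s': split on '%s' dropped (subset of %d < %d rows)",
          cl, feat, min(sizes), min_subset_size))
      } else {
        branch <- proposal
      }
    }
    subsets <- c(subsets, branch)
  }
  subsets <- lapply(subsets, function(b) {
    list(label = b$label, data = dataset_slice(ds, b$idx))
  })
  for (msg in dropped) message("build_partition: ", msg)
  structure(list(subsets = subsets, target = target,
                 criteria = criteria, dropped = dropped),
            class = "dc_partition")
}

partition_label_string <- function(label) {
  paste(sprintf("%s-%s", names(label), unlist(label)), collapse = "__")
}

#' @export
print.dc_partition <- function(x, ...) {
  cat(sprintf("<dc_partition> %d subset(s)\n", length(x$subsets)))
  for (s in x$subsets) {
    cat(sprintf("  %-40s %6d rows\n",
                partition_label_string(s$label), n_rows(s$data)))
  }
  if (length(x$dropped)) {
    cat("  guards: ", paste(x$dropped, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}
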