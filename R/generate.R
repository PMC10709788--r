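# The "conquer" step and the end-to-end divide-and-conquer synthesizer.

#' Allocate synthetic volume across partition subsets
#'
#' Splits a total synthetic volume over the partition's subsets. Class
#' totals follow `class_ratio` (event : non-event weights): the minority
#' class receives `round(total * min(w) / sum(w))` rows — so a 1:100 ratio
#' at total 5000 gives `round(5000 / 101) = 50` minority rows — and the
#' majority the remainder. Within a class, rows are apportioned across that
#' class's subsets proportionally to their original-data sizes with
#' largest-remainder rounding, so the total is conserved exactly.
#'
#' @param partition A `dc_partition` from [build_partition()].
#' @param total Total synthetic rows (>= number of classes).
#' @param class_ratio Length-2 positive weights, ordered (event class,
#'   non-event class). `c(1, 1)` is balanced 50:50; `c(1, 100)` makes the
#'   event class 100 times rarer.
#' @param event_level Optional explicit event-class label (defaults to the
#'   target's second category).
#' @return An object of class `volume_plan`: list with `total`,
#'   `class_totals` (named), and `per_subset` (named integer vector keyed
#'   by subset label).
#' @export
allocate_volumes <- function(partition, total, class_ratio = c(1, 1),
                             event_level = NULL) {
  stopifnot(inherits(partition, "dc_partition"))
  if (!is_count(total, min = 2L)) abort("total must be an integer >= 2")
  if (length(class_ratio) != 2L || any(class_ratio <= 0)) {
    abort("class_ratio must be two positive weights")
  }
  schema <- partition$subsets[[1L]]$data$schema
  event <- target_event_class(schema, event_level)
  classes <- schema$columns[[partition$target]]$categories
  nonevent <- setdiff(classes, event)
  w <- stats::setNames(class_ratio, c(event, nonevent))
  minority_class <- names(w)[which.min(w)]
  minority_n <- as.integer(round(total * min(w) / sum(w)))
  class_totals <- stats::setNames(c(minority_n, total - minority_n),
                                  c(minority_class,
                                    setdiff(names(w), minority_class)))
  subset_labels <- vapply(partition$subsets,
                          function(s) partition_label_string(s$label),
                          character(1))
  subset_class <- vapply(partition$subsets,
                         function(s) s$label[[partition$target]], character(1))
  subset_size <- vapply(partition$subsets, function(s) n_rows(s$data),
                        numeric(1))
  per_subset <- stats::setNames(integer(length(subset_labels)), subset_labels)
  for (cl in classes) {
    idx <- which(subset_class == cl)
    if (!length(idx)) abort("class '%s' has no subsets in the partition", cl)
    per_subset[idx] <- largest_remainder(class_totals[[cl]], subset_size[idx])
  }
  structure(list(total = as.integer(total), class_totals = class_totals,
                 per_subset = per_subset),
            class = "volume_plan")
}

#' @export
print.volume_plan <- function(x, ...) {
  cat(sprintf("<volume_plan> total %d (%s)\n", x$total,
              paste(sprintf("%s: %d", names(x$class_totals), x$class_totals),
                    collapse = ", ")))
  for (nm in names(x$per_subset)) {
    cat(sprintf("  %-40s %6d\n", nm, x$per_subset[[nm]]))
  }
  invisible(x)
}

#' Recombine per-subset synthetic samples
#'
#' Concatenates the per-subset samples into one table and applies a seeded
#' uniform shuffle, so downstream train/test splits are not biased by
#' subset order.
#'
#' @param subset_samples Non-empty list of [tabular_dataset()] objects
#'   sharing one schema.
#' @param seed Integer seed for the shuffle.
#' @return A [tabular_dataset()] with `sum(rows)` rows.
#' @export
conquer <- function(subset_samples, seed) {
  if (!length(subset_samples)) abort("conquer needs at least one sample")
  combined <- dataset_bind(subset_samples)
  with_seed(seed, dataset_slice(combined, sample.int(n_rows(combined))))
}

# backend registry -----------------------------------------------------------

#' Generator backend contract
#'
#' A backend is a `fit(ds) -> model` / `sample(model, n) -> dataset` pair
#' plus a (possibly empty) hyperparameter grid for [backend_sweep()]. The
#' in-repo backends are `"copula"` (Gaussian copula, the reference) and
#' `"independent"` (same marginals, identity dependence). External
#' generators — e.g. neural tabular GAN implementations — attach by
#' supplying their own pair; `sample` is called inside a seeded RNG scope,
#' so backends drawing from R's RNG are deterministic automatically.
#'
#' @param backend A backend name or a list with elements `fit`, `sample`
#'   and optionally `grid` (named list of hyperparameter value vectors).
#' @return A validated backend list.
#' @export
generator_backend <- function(backend = c("copula", "independent")) {
  if (is.character(backend)) {
    backend <- match.arg(backend)
    return(switch(backend,
      copula = list(name = "copula", fit = fit_copula,
                    sample = sample_copula_impl, grid = list()),
      independent = list(name = "independent", fit = fit_independent,
                         sample = sample_copula_impl, grid = list())))
  }
  if (!is.list(backend) || !is.function(backend$fit) ||
      !is.function(backend$sample)) {
    abort("a backend must provide fit(ds) and sample(model, n) functions")
  }
  backend$grid <- backend$grid %||% list()
  backend$name <- backend$name %||% "custom"
  backend
}

# dc_synth: the fitted divide-and-conquer synthesizer ------------------------

#' Fit a divide-and-conquer synthesizer
#'
#' The core fitting function. Three stages: (1) *divide criteria* — the
#' Cramer V matrix over all column pairs (numerics discretized with a
#' point-mass carve-out) is scanned for perfectly associated pairs, and
#' each pair's main attribute becomes a division feature; (2) *divide* —
#' the data are cross-partitioned by outcome class and by the division
#' features, guarded by `min_subset_size`; (3) per-subset generator fits
#' with the chosen backend. Because every logical rule's trigger column is
#' fixed within a subset and the dependent column is constant there, the
#' sampled data satisfy the rules by construction — no rejection filtering,
#' no discarded records.
#'
#' @param ds A [tabular_dataset()] (the original data).
#' @param backend Backend name or contract, see [generator_backend()].
#' @param n_bins Bins for numeric discretization in the association scan.
#' @param threshold Cramer V division threshold (default 1).
#' @param min_subset_size Subset-size guard for [build_partition()].
#' @return An object of class `dc_synth` with components `vmat`, `pairs`,
#'   `criteria`, `partition`, `models` (one per subset), `backend`,
#'   `schema`.
#' @seealso [simulate.dc_synth()], [generate_std()]
#' @export
#' @examples
#' fx <- generate_fixture(fixture_params(n = 400, seed = 1))
#' fit <- dc_synth(fx$data)
#' fit
#' syn <- simulate(fit, nsim = 200, seed = 2)
dc_synth <- function(ds, backend = "copula", n_bins = 10L, threshold = 1,
                     min_subset_size = 50L) {
  stopifnot(inherits(ds, "tabular_dataset"))
  backend <- generator_backend(backend)
  vmat <- cramers_v_matrix(ds, n_bins)
  pairs <- find_division_pairs(vmat, threshold, target = ds$schema$target)
  criteria <- division_criteria(ds, pairs, n_bins)
  partition <- build_partition(ds, criteria, min_subset_size)
  models <- lapply(partition$subsets, function(s) backend$fit(s$data))
  names(models) <- vapply(partition$subsets,
                          function(s) partition_label_string(s$label),
                          character(1))
  structure(list(vmat = vmat, pairs = pairs, criteria = criteria,
                 partition = partition, models = models, backend = backend,
                 schema = ds$schema, n_train = n_rows(ds)),
            class = "dc_synth")
}

#' @export
print.dc_synth <- function(x, ...) {
  cat(sprintf("<dc_synth> %s backend, fitted on %d rows\n",
              x$backend$name, x$n_train))
  cat(sprintf("  division features: %s\n",
              if (length(x$criteria$division_features))
                paste(x$criteria$division_features, collapse = ", ")
              else "(none; class split only)"))
  cat(sprintf("  subsets: %s\n",
              paste(sprintf("%s (%d)", names(x$models),
                            vapply(x$partition$subsets,
                                   function(s) n_rows(s$data), numeric(1))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.dc_synth <- function(object, ...) {
  cat(sprintf("Divide-and-conquer synthesizer (%s backend)\n",
              object$backend$name))
  cat(sprintf("Training rows: %d; target: '%s'\n", object$n_train,
              object$schema$target))
  if (nrow(object$pairs)) {
    cat("Perfect-association pairs (Cramer V >= threshold):\n")
    print(object$pairs, row.names = FALSE)
  } else {
    cat("No perfect-association pairs; class-specific split only.\n")
  }
  print(object$partition)
  invisible(object)
}

#' Simulate synthetic data from a fitted synthesizer
#'
#' Draws the per-subset volumes from [allocate_volumes()], samples each
#' subset's generator, and recombines with a seeded shuffle.
#'
#' @param object A [dc_synth()] fit.
#' @param nsim Total synthetic rows (default 5000).
#' @param seed Integer seed (required for reproducibility).
#' @param class_ratio Event : non-event weights, see [allocate_volumes()].
#' @param ... Unused.
#' @return A [tabular_dataset()] with `nsim` rows; the realized volume
#'   plan is attached as attribute `"volume_plan"`.
#' @export
simulate.dc_synth <- function(object, nsim = 5000L, seed = NULL,
                              class_ratio = c(1, 1), ...) {
  if (is.null(seed)) abort("simulate.dc_synth requires an integer seed")
  plan <- allocate_volumes(object$partition, nsim, class_ratio)
  out <- with_seed(seed, {
    parts <- Map(function(model, k) object$backend$sample(model, k),
                 object$models, plan$per_subset[names(object$models)])
    combined <- dataset_bind(parts)
    dataset_slice(combined, sample.int(n_rows(combined)))
  })
  attr(out, "volume_plan") <- plan
  out
}

# one-call pipeline -----------------------------------------------------------

#' Generate synthetic tabular data end to end
#'
#' One-call wrapper over the three strategies compared in the package:
#' `"dc"` fits a [dc_synth()] (divide by class and by perfect-association
#' features, fit per subset, sample, recombine); `"cs"` fits one backend on
#' the whole table and filters with [rejection_sample()] against `rules`;
#' `"none"` fits one backend on the whole table and samples without any
#' constraint handling (the arm that produces impossible records).
#' Class-balance control applies to the DC strategy, where the class split
#' makes exact allocation possible; CS and none reproduce the original
#' class marginal.
#'
#' @param ds A [tabular_dataset()].
#' @param rules Logical rules (default: the schema's rules). Used by the
#'   `"cs"` strategy only; DC needs none.
#' @param strategy `"dc"`, `"cs"` or `"none"`.
#' @param backend Backend name or contract.
#' @param total Synthetic rows to produce (default 5000).
#' @param class_ratio Event : non-event weights (DC only), default balanced.
#' @param seed Integer seed.
#' @param n_bins,threshold,min_subset_size Forwarded to [dc_synth()].
#' @param max_batches Rejection-sampling batch cap (CS only).
#' @return A [tabular_dataset()] with `total` rows.
#' @export
generate_std <- function(ds, rules = ds$schema$rules,
                         strategy = c("dc", "cs", "none"),
                         backend = "copula", total = 5000L,
                         class_ratio = c(1, 1), seed = 1L,
                         n_bins = 10L, threshold = 1,
                         min_subset_size = 50L, max_batches = 100L) {
  strategy <- match.arg(strategy)
  if (strategy == "dc") {
    fit <- dc_synth(ds, backend = backend, n_bins = n_bins,
                    threshold = threshold,
                    min_subset_size = min_subset_size)
    return(simulate(fit, nsim = total, seed = seed,
                    class_ratio = class_ratio))
  }
  bk <- generator_backend(backend)
  model <- bk$fit(ds)
  if (strategy == "cs") {
    rejection_sample(model, rules, total, seed, max_batches)
  } else {
    with_seed(seed, bk$sample(model, total))
  }
}
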