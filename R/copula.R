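# Gaussian-copula reference generator: empirical marginals coupled through
# a correlation matrix on normal scores.

#' Fit a Gaussian copula generator to a (sub)dataset
#'
#' Marginals are kept empirical: numeric columns store their sorted training
#' values (empirical CDF / inverse CDF), categorical columns store category
#' frequencies mapped to contiguous sub-intervals of `[0, 1]`. Each training
#' cell is mapped to a normal score — numeric via `qnorm((rank - 0.5) / n)`,
#' categorical via the normal quantile of its interval midpoint — and the
#' dependence structure is the Pearson correlation of those scores, repaired
#' to the nearest positive semidefinite correlation matrix if needed.
#'
#' A subset with a single row degenerates to row replication (warned): there
#' is no dependence to estimate from one observation.
#'
#' @param ds A [tabular_dataset()] with at least one row.
#' @return An object of class `copula_model`.
#' @export
fit_copula <- function(ds) {
  stopifnot(inherits(ds, "tabular_dataset"))
  n <- n_rows(ds)
  if (n == 0L) abort("cannot fit a generator on an empty subset")
  if (n == 1L) {
    warning("fitting on a single row: sampling degenerates to row replication")
  }
  cols <- schema_colnames(ds$schema)
  marginals <- list()
  scores <- matrix(0, nrow = n, ncol = length(cols),
                   dimnames = list(NULL, cols))
  for (cn in cols) {
    x <- ds$data[[cn]]
    if (schema_kind(ds$schema, cn) == "numeric") {
      sorted <- sort(as.numeric(x))
      marginals[[cn]] <- list(kind = "numeric", sorted = sorted)
      scores[, cn] <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
    } else {
      cats <- ds$schema$columns[[cn]]$categories
      probs <- as.numeric(table(factor(x, levels = cats))) / n
      cum <- cumsum(probs)
      marginals[[cn]] <- list(kind = "categorical", categories = cats,
                              probs = probs, cum = cum)
      lower <- c(0, cum[-length(cum)])
      mid <- (lower + cum) / 2
      scores[, cn] <- stats::qnorm(mid[match(as.character(x), cats)])
    }
  }
  dependence <- score_correlation(scores)
  structure(list(schema = ds$schema, marginals = marginals,
                 dependence = dependence, n_train = n),
            class = "copula_model")
}

#' Fit an independence baseline generator
#'
#' Identical marginals to [fit_copula()] but with an identity dependence
#' matrix: every column is sampled independently. This deliberately destroys
#' all pair trends and serves as the ablation baseline for the fidelity
#' metrics.
#'
#' @param ds A [tabular_dataset()].
#' @return A `copula_model` with identity dependence.
#' @export
fit_independent <- function(ds) {
  model <- fit_copula(ds)
  p <- nrow(model$dependence)
  model$dependence <- diag(1, p)
  dimnames(model$dependence) <- list(schema_colnames(model$schema),
                                     schema_colnames(model$schema))
  model
}

# Pearson correlation of normal scores; constant columns get 0 off-diagonal;
# repaired to nearest PSD correlation matrix when estimation noise pushes an
# eigenvalue negative.
score_correlation <- function(scores) {
  p <- ncol(scores)
  sds <- apply(scores, 2, stats::sd)
  R <- diag(1, p)
  dimnames(R) <- list(colnames(scores), colnames(scores))
  ok <- which(sds > 0 & is.finite(sds))
  if (length(ok) >= 2) {
    R[ok, ok] <- stats::cor(scores[, ok, drop = FALSE])
  }
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  }
  R
}

#' @export
print.copula_model <- function(x, ...) {
  cat(sprintf("<copula_model> %d columns, fitted on %d rows\n",
              length(x$marginals), x$n_train))
  invisible(x)
}

# sampling ------------------------------------------------------------------

#' Sample synthetic rows from a fitted copula model
#'
#' Draws multivariate normal vectors with the model's dependence, maps each
#' coordinate through the standard normal CDF to `u` in `[0, 1]`, and
#' inverts the stored marginals: numeric columns by linear interpolation
#' between sorted training values (output confined to the training range —
#' this is what makes structural zeros of a constant subset reproduce
#' exactly), categorical columns by locating `u` in the category's
#' frequency interval. Deterministic given `seed`.
#'
#' @param model A `copula_model`.
#' @param n Number of rows to draw (>= 0).
#' @param seed Integer seed.
#' @return A [tabular_dataset()] with the model's schema.
#' @export
sample_copula <- function(model, n, seed) {
  stopifnot(inherits(model, "copula_model"), is_count(n))
  with_seed(seed, sample_copula_impl(model, n))
}

#' @rdname sample_copula
#' @export
sample_independent <- function(model, n, seed) sample_copula(model, n, seed)

# uses the current RNG state (callers own the seed)
sample_copula_impl <- function(model, n) {
  cols <- names(model$marginals)
  p <- length(cols)
  if (n == 0L) {
    empty <- stats::setNames(
      lapply(cols, function(cn) {
        m <- model$marginals[[cn]]
        if (m$kind == "numeric") numeric(0)
        else factor(character(0), levels = m$categories)
      }), cols)
    return(tabular_dataset(as.data.frame(empty, check.names = FALSE),
                           model$schema))
  }
  # eigendecomposition handles semidefinite dependence (perfect correlation)
  eg <- eigen(model$dependence, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), p)
  Z <- matrix(stats::rnorm(n * p), nrow = n) %*% t(L)
  U <- stats::pnorm(Z)
  out <- vector("list", p)
  names(out) <- cols
  for (j in seq_len(p)) {
    m <- model$marginals[[cols[j]]]
    u <- U[, j]
    if (m$kind == "numeric") {
      out[[j]] <- inv_ecdf(m$sorted, u)
    } else {
      # u in (0,1) strictly, so zero-width (unseen-category) intervals are
      # unreachable: findInterval skips repeated cumulative values
      idx <- findInterval(u, m$cum) + 1L
      idx[idx > length(m$categories)] <- length(m$categories)
      out[[j]] <- factor(m$categories[idx], levels = m$categories)
    }
  }
  tabular_dataset(as.data.frame(out, check.names = FALSE), model$schema)
}

# empirical inverse CDF: linear interpolation between sorted training values
# at plotting positions (i - 0.5)/n, clamped to the training range
inv_ecdf <- function(sorted, u) {
  n <- length(sorted)
  if (n == 1L) return(rep(sorted, length(u)))
  probs <- (seq_len(n) - 0.5) / n
  stats::approx(probs, sorted, xout = u, rule = 2, ties = "ordered")$y
}

#' Rejection sampling against logical rules (conditional sampling)
#'
#' The conditional-sampling baseline: repeatedly draws batches of `n` rows
#' from the model, keeps only rows violating no rule, and stops once `n`
#' valid rows have accumulated. Fails with the observed acceptance rate if
#' `max_batches` batches do not suffice — the signature of over-constrained
#' conditions, and the cost this strategy pays for discarding records.
#'
#' @param model A `copula_model`.
#' @param rules List of [logical_rule()] objects.
#' @param n Rows required (>= 0).
#' @param seed Integer seed.
#' @param max_batches Batch cap (default 100).
#' @return A [tabular_dataset()] of exactly `n` rule-satisfying rows, with
#'   attributes `acceptance_rate` (valid / drawn) and `batches_used`.
#' @export
rejection_sample <- function(model, rules, n, seed, max_batches = 100L) {
  stopifnot(inherits(model, "copula_model"), is_count(n),
            is_count(max_batches, min = 1L))
  with_seed(seed, {
    kept <- list()
    n_kept <- 0L
    n_drawn <- 0L
    batches <- 0L
    while (n_kept < n && batches < max_batches) {
      batches <- batches + 1L
      batch <- sample_copula_impl(model, max(n, 1L))
      n_drawn <- n_drawn + n_rows(batch)
      ok <- !row_violates(batch, rules)
      if (any(ok)) {
        kept[[length(kept) + 1L]] <- dataset_slice(batch, which(ok))
        n_kept <- n_kept + sum(ok)
      }
    }
    if (n_kept < n) {
      abort(paste0("rejection sampling exhausted %d batches with acceptance ",
                   "rate %.4f (%d/%d valid); conditions are over-constrained"),
            batches, if (n_drawn) n_kept / n_drawn else 0, n_kept, n_drawn)
    }
    out <- if (length(kept)) dataset_bind(kept)
           else sample_copula_impl(model, 0L)
    out <- dataset_slice(out, seq_len(n))
    attr(out, "acceptance_rate") <- if (n_drawn) n_kept / n_drawn else 1
    attr(out, "batches_used") <- batches
    out
  })
}

# logical-rule violation indicator per row (shared with violation_report)
row_violates <- function(ds, rules, tol = 1e-9) {
  viol <- rep(FALSE, n_rows(ds))
  for (r in rules) {
    for (cn in c(r$trigger_column, r$dependent_column)) {
      if (!cn %in% schema_colnames(ds$schema)) {
        abort("rule references unknown column '%s'", cn)
      }
    }
    armed <- as.character(ds$data[[r$trigger_column]]) == r$trigger_value
    dep <- ds$data[[r$dependent_column]]
    bad <- if (is.numeric(dep)) {
      abs(dep - as.numeric(r$required_value)) > tol
    } else {
      as.character(dep) != as.character(r$required_value)
    }
    viol <- viol | (armed & bad)
  }
  viol
}
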