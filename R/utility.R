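# Train-on-synthetic / test-on-real (TSTR) evaluation harness.

#' Stratified train/validation split
#'
#' Per target class, `round(train_fraction * class size)` rows are sampled
#' (seeded) into the training set; the rest form the validation set. The
#' two parts are disjoint and their union is the input.
#'
#' @param ds A [tabular_dataset()].
#' @param train_fraction Fraction in (0, 1); default 0.7.
#' @param seed Integer seed.
#' @return List with elements `train` and `validation`.
#' @export
stratified_split <- function(ds, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(ds, "tabular_dataset"))
  if (!is_prob(train_fraction)) abort("train_fraction must lie in (0, 1)")
  target <- ds$schema$target
  cls <- as.character(ds$data[[target]])
  classes <- ds$schema$columns[[target]]$categories
  train_idx <- integer(0)
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(cls == cl)
      if (length(idx) < 2L) {
        abort("class '%s' has fewer than 2 rows; cannot split", cl)
      }
      k <- round(train_fraction * length(idx))
      k <- min(max(k, 1L), length(idx) - 1L)
      train_idx <- c(train_idx, sample(idx, k))
    }
  })
  train_idx <- sort(train_idx)
  list(train = dataset_slice(ds, train_idx),
       validation = dataset_slice(ds, setdiff(seq_len(n_rows(ds)), train_idx)))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs
#' where the positive's score exceeds the negative's, ties counted one
#' half — identical to the trapezoidal area under the ROC curve.
#'
#' @param labels Binary labels (0/1, logical, or two-level factor with the
#'   second level positive).
#' @param scores Numeric scores, higher meaning more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  labels <- as_binary_labels(labels)
  if (length(labels) != length(scores)) abort("labels/scores length mismatch")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort("auc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) > 2) abort("labels must be binary")
    return(as.integer(labels == levels(labels)[2L]))
  }
  if (is.logical(labels)) return(as.integer(labels))
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) abort("labels must be binary (0/1)")
  as.integer(labels)
}

#' F1 score for binary predictions
#'
#' Per-class F1 is `2 * precision * recall / (precision + recall)` with the
#' undefined-as-0 convention. `average = "macro"` (default) returns the
#' unweighted mean of the two per-class F1 values — the convention under
#' which a majority-class-collapsed classifier on balanced labels scores
#' 1/3 rather than 0; `"positive"` returns the event-class F1 alone.
#'
#' @param labels Binary true labels.
#' @param predictions Binary predicted labels.
#' @param average `"macro"` or `"positive"`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(labels, predictions, average = c("macro", "positive")) {
  average <- match.arg(average)
  labels <- as_binary_labels(labels)
  predictions <- as_binary_labels(predictions)
  if (length(labels) != length(predictions)) {
    abort("labels/predictions length mismatch")
  }
  f1_one <- function(pos) {
    tp <- sum(labels == pos & predictions == pos)
    fp <- sum(labels != pos & predictions == pos)
    fn <- sum(labels == pos & predictions != pos)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  if (average == "positive") f1_one(1L) else mean(c(f1_one(1L), f1_one(0L)))
}

# feature encoding ------------------------------------------------------------

# one-hot encode categoricals (all schema levels, so unseen-at-train levels
# never fail), numeric passthrough; returns a plain numeric matrix
encode_features <- function(ds) {
  cols <- schema_feature_names(ds$schema)
  mats <- lapply(cols, function(cn) {
    x <- ds$data[[cn]]
    if (schema_kind(ds$schema, cn) == "numeric") {
      m <- matrix(as.numeric(x), ncol = 1)
      colnames(m) <- cn
      m
    } else {
      lev <- ds$schema$columns[[cn]]$categories
      m <- outer(as.character(x), lev, `==`) * 1
      colnames(m) <- paste(cn, lev, sep = ".")
      m
    }
  })
  do.call(cbind, mats)
}

dataset_labels <- function(ds, event_level = NULL) {
  ev <- target_event_class(ds$schema, event_level)
  as.integer(as.character(ds$data[[ds$schema$target]]) == ev)
}

#' Classifier adapters
#'
#' Returns a classifier contract — `fit(x, y, seed) -> model` and
#' `predict_proba(model, x) -> event probabilities` — for one of the
#' built-in families: `"dt"` (CART decision tree, rpart), `"rf"` (random
#' forest, ranger), `"xgb"` (gradient-boosted trees, xgboost) or `"logit"`
#' (regularized-free logistic regression, glm). Hyperparameters are fixed
#' and small; single-threaded so repeated runs are bit-reproducible.
#'
#' @param name Adapter name.
#' @return List with `name`, `fit`, `predict_proba`.
#' @export
classifier_adapter <- function(name = c("dt", "rf", "xgb", "logit")) {
  name <- match.arg(name)
  switch(name,
    dt = list(
      name = "dt",
      fit = function(x, y, seed) {
        df <- data.frame(.y = factor(y, levels = c(0, 1)), x,
                         check.names = FALSE)
        with_seed(seed, rpart::rpart(.y ~ ., data = df, method = "class",
                                     cp = 0.002, minsplit = 20))
      },
      predict_proba = function(model, x) {
        stats::predict(model, data.frame(x, check.names = FALSE))[, "1"]
      }),
    rf = list(
      name = "rf",
      fit = function(x, y, seed) {
        df <- data.frame(.y = factor(y, levels = c(0, 1)), x,
                         check.names = FALSE)
        ranger::ranger(.y ~ ., data = df, probability = TRUE,
                       num.trees = 200, seed = seed, num.threads = 1)
      },
      predict_proba = function(model, x) {
        stats::predict(model, data.frame(x, check.names = FALSE),
                       num.threads = 1)$predictions[, "1"]
      }),
    xgb = list(
      name = "xgb",
      fit = function(x, y, seed) {
        dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
        with_seed(seed, xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 4,
                        eta = 0.2, nthread = 1),
          data = dtrain, nrounds = 50, verbose = 0))
      },
      predict_proba = function(model, x) {
        stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x)))
      }),
    logit = list(
      name = "logit",
      fit = function(x, y, seed) {
        df <- data.frame(.y = y, x, check.names = FALSE)
        suppressWarnings(stats::glm(.y ~ ., data = df,
                                    family = stats::binomial()))
      },
      predict_proba = function(model, x) {
        stats::predict(model, data.frame(x, check.names = FALSE),
                       type = "response")
      })
  )
}

#' Train-on-synthetic / test-on-real evaluation
#'
#' For each seed: fit the classifier on the training table (one-hot encoded
#' categoricals, numeric passthrough), score the real validation table,
#' and record AUC (on predicted event probability) and F1 (predictions
#' thresholded at 0.5). Aggregates mean and SD (population formula,
#' `n` divisor) over the repeats.
#'
#' @param train Training [tabular_dataset()] (synthetic or real).
#' @param validation Real held-out [tabular_dataset()] with one schema.
#' @param classifier Adapter name or contract from [classifier_adapter()].
#' @param seeds Integer vector of repeat seeds (default `1:5`).
#' @param f1_average Forwarded to [f1_score()].
#' @return An object of class `utility_result`: `per_seed` data frame and
#'   `mean_auc`, `sd_auc`, `mean_f1`, `sd_f1`.
#' @export
tstr_evaluate <- function(train, validation, classifier = "rf",
                          seeds = 1:5, f1_average = "macro") {
  if (is.character(classifier)) classifier <- classifier_adapter(classifier)
  if (!identical(schema_colnames(train$schema),
                 schema_colnames(validation$schema))) {
    abort("train and validation must share one schema")
  }
  x_tr <- encode_features(train)
  y_tr <- dataset_labels(train)
  x_va <- encode_features(validation)
  y_va <- dataset_labels(validation)
  rows <- lapply(seeds, function(s) {
    model <- tryCatch(classifier$fit(x_tr, y_tr, s),
                      error = function(e) abort(
                        "classifier '%s' failed at seed %d: %s",
                        classifier$name, s, conditionMessage(e)))
    p <- classifier$predict_proba(model, x_va)
    data.frame(seed = s,
               auc = auc(y_va, p),
               f1 = f1_score(y_va, as.integer(p >= 0.5),
                             average = f1_average))
  })
  per_seed <- do.call(rbind, rows)
  structure(list(per_seed = per_seed,
                 mean_auc = mean(per_seed$auc), sd_auc = pop_sd(per_seed$auc),
                 mean_f1 = mean(per_seed$f1), sd_f1 = pop_sd(per_seed$f1),
                 classifier = classifier$name),
            class = "utility_result")
}

#' @export
print.utility_result <- function(x, ...) {
  cat(sprintf(
    "<utility_result> %s over %d seed(s): AUC %.2f (%.2f), F1 %.2f (%.2f)\n",
    x$classifier, nrow(x$per_seed), 100 * x$mean_auc, 100 * x$sd_auc,
    100 * x$mean_f1, 100 * x$sd_f1))
  invisible(x)
}

#' Full strategy-by-balance experiment grid
#'
#' Crosses generation strategies, backends and class balances; for each
#' cell, generates synthetic data from the development split, evaluates
#' fidelity against the development data, checks logical-rule violations,
#' and runs TSTR against the real validation split with every classifier.
#' A `"real"` reference row (training directly on the development data) is
#' included for comparison.
#'
#' @param ds Original data ([tabular_dataset()]).
#' @param rules Logical rules (default: schema rules).
#' @param strategies Subset of `c("dc", "cs", "none")`.
#' @param backends Character vector of backend names.
#' @param balances Named list of class-ratio pairs, e.g.
#'   `list("50:50" = c(1, 1), "1:100" = c(1, 100))`.
#' @param classifiers Character vector of adapter names.
#' @param seeds Repeat seeds for TSTR.
#' @param total Synthetic volume per cell (default 5000).
#' @param train_fraction,split_seed Development/validation split control.
#' @return A data frame with one row per (strategy, backend, balance,
#'   classifier): utility means/SDs, fidelity aggregates, violation rate.
#' @export
experiment_grid <- function(ds, rules = ds$schema$rules,
                            strategies = c("dc", "cs", "none"),
                            backends = "copula",
                            balances = list("50:50" = c(1, 1)),
                            classifiers = c("dt", "rf"),
                            seeds = 1:5, total = 5000L,
                            train_fraction = 0.7, split_seed = 1L) {
  split <- stratified_split(ds, train_fraction, split_seed)
  dev <- split$train
  val <- split$validation
  out <- list()
  add_row <- function(strategy, backend, balance, train_data) {
    fr <- if (identical(train_data, dev)) NULL
          else quality_report(dev, train_data)
    vr <- violation_report(train_data, rules)
    for (clf in classifiers) {
      ur <- tstr_evaluate(train_data, val, clf, seeds)
      out[[length(out) + 1L]] <<- data.frame(
        strategy = strategy, backend = backend, balance = balance,
        classifier = clf,
        mean_auc = ur$mean_auc, sd_auc = ur$sd_auc,
        mean_f1 = ur$mean_f1, sd_f1 = ur$sd_f1,
        shape = if (is.null(fr)) NA_real_ else fr$shape,
        pair_trend = if (is.null(fr)) NA_real_ else fr$pair_trend,
        overall = if (is.null(fr)) NA_real_ else fr$overall,
        violation_rate = vr$violation_rate,
        stringsAsFactors = FALSE)
    }
  }
  add_row("real", "-", "-", dev)
  for (strategy in strategies) {
    for (backend in backends) {
      for (bal in names(balances)) {
        if (strategy != "dc" && bal != names(balances)[1L]) next
        std <- generate_std(dev, rules, strategy = strategy,
                            backend = backend, total = total,
                            class_ratio = balances[[bal]],
                            seed = split_seed)
        add_row(strategy, backend,
                if (strategy == "dc") bal else "od-marginal", std)
      }
    }
  }
  do.call(rbind, out)
}
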