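test_that("auc matches anchor cases and the pair-counting oracle", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_equal(auc(c(0, 1, 0, 1), c(0.4, 0.3, 0.2, 0.8)), 0.75)
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(3)
  for (i in 1:60) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(seq(0, 1, 0.1), n, TRUE)  # force ties
    expect_equal(auc(labels, scores), oracle_auc(labels, scores),
                 tolerance = 1e-12)
    # invariance to strictly monotone score transforms
    expect_equal(auc(labels, exp(3 * scores)), auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("macro F1 follows the stated per-class formulas", {
  expect_equal(f1_score(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  # positive: TP=2 FP=1 FN=1, negative mirrored -> per-class 2/3, macro 2/3
  labels <- c(1, 1, 1, 0, 0, 0)
  preds <- c(1, 1, 0, 1, 0, 0)
  expect_equal(f1_score(labels, preds), 2 / 3)
  expect_equal(f1_score(labels, preds, average = "positive"), 2 / 3)
  # all-one-class predictions on balanced labels -> macro 1/3
  expect_equal(f1_score(c(0, 0, 1, 1), c(1, 1, 1, 1)), 1 / 3)
  # all wrong -> 0
  expect_equal(f1_score(c(0, 1), c(1, 0)), 0)
})

test_that("stratified split respects per-class rounding, determinism and
           reassembly", {
  fx <- generate_fixture(fixture_params(n = 100, event_prevalence = 0.5,
                                        seed = 30))
  sp <- stratified_split(fx$data, 0.7, seed = 1)
  cls_tr <- table(sp$train$data$adverse_event)
  cls_all <- table(fx$data$data$adverse_event)
  for (cl in names(cls_all)) {
    expect_equal(unname(cls_tr[cl]), round(0.7 * unname(cls_all[cl])))
  }
  expect_equal(n_rows(sp$train) + n_rows(sp$validation), 100L)
  expect_equal(sort(c(row_keys(sp$train), row_keys(sp$validation))),
               sort(row_keys(fx$data)))

  sp2 <- stratified_split(fx$data, 0.7, seed = 1)
  expect_identical(sp$train$data, sp2$train$data)

  # class proportions preserved within one row per class
  for (seed in 1:5) {
    fx2 <- generate_fixture(fixture_params(n = 157, event_prevalence = 0.37,
                                           seed = seed))
    sp3 <- stratified_split(fx2$data, 0.61, seed = seed)
    cls3 <- table(fx2$data$data$adverse_event)
    tr3 <- table(sp3$train$data$adverse_event)
    for (cl in names(cls3)) {
      expect_lte(abs(unname(tr3[cl]) - 0.61 * unname(cls3[cl])), 1)
    }
  }
})

test_that("tstr is perfect on separable data and reproducible per seed", {
  # linearly separable toy: one numeric feature fully determines the class
  schema <- tabular_schema(
    list(col_schema("y", "categorical", c("neg", "pos"), role = "target"),
         col_schema("x", "numeric")))
  set.seed(4)
  df <- data.frame(y = rep(c("neg", "pos"), each = 50),
                   x = c(rnorm(50, 0), rnorm(50, 10)))
  ds <- tabular_dataset(df, schema)
  res <- tstr_evaluate(ds, ds, "dt", seeds = 1:2)
  expect_equal(res$mean_auc, 1)
  expect_equal(res$sd_auc, 0)

  res2 <- tstr_evaluate(ds, ds, "dt", seeds = 1:2)
  expect_identical(res$per_seed, res2$per_seed)
})

test_that("a label-independent classifier scores chance-level AUC", {
  random_clf <- list(
    name = "coin",
    fit = function(x, y, seed) seed,
    predict_proba = function(model, x) {
      dcsynth:::with_seed(model, runif(nrow(x)))
    })
  fx <- generate_fixture(fixture_params(n = 1000, seed = 40))
  sp <- stratified_split(fx$data, 0.7, seed = 2)
  res <- tstr_evaluate(sp$train, sp$validation, random_clf, seeds = 1:5)
  expect_equal(res$mean_auc, 0.5, tolerance = 0.1)
})

test_that("mean/SD aggregates are recomputable from per-seed entries with
           the population formula", {
  fx <- generate_fixture(fixture_params(n = 600, seed = 41))
  sp <- stratified_split(fx$data, 0.7, seed = 1)
  res <- tstr_evaluate(sp$train, sp$validation, "dt", seeds = 1:3)
  expect_equal(res$mean_auc, mean(res$per_seed$auc))
  n <- nrow(res$per_seed)
  expect_equal(res$sd_auc,
               sqrt(sum((res$per_seed$auc - mean(res$per_seed$auc))^2) / n))
})

test_that("every built-in classifier adapter runs the contract end to end", {
  fx <- generate_fixture(fixture_params(n = 500, seed = 42))
  sp <- stratified_split(fx$data, 0.7, seed = 3)
  for (clf in c("dt", "rf", "xgb", "logit")) {
    res <- tstr_evaluate(sp$train, sp$validation, clf, seeds = 1L)
    expect_true(res$per_seed$auc > 0.5, info = clf)
  }
})

test_that("experiment_grid crosses strategies and reports the expected
           columns", {
  fx <- generate_fixture(fixture_params(n = 1000, seed = 44))
  grid <- experiment_grid(fx$data, strategies = c("dc", "none"),
                          classifiers = "dt", seeds = 1:2, total = 400,
                          split_seed = 1)
  expect_true(all(c("strategy", "mean_auc", "overall", "violation_rate")
                  %in% names(grid)))
  expect_setequal(unique(grid$strategy), c("real", "dc", "none"))
  expect_equal(grid$violation_rate[grid$strategy == "dc"], 0)
  expect_gt(grid$violation_rate[grid$strategy == "none"], 0)
})
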