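test_that("copula marginals store frequencies as interval widths and a
           constant column propagates exactly", {
  ds <- toy_dataset(5L)
  model <- fit_copula(ds)
  m <- model$marginals$smoker
  expect_equal(m$probs, c(0.5, 0.5))
  expect_equal(m$cum, c(0.5, 1))

  # survival-nonsmoker style subset: pack_years constant 0
  sub <- dcsynth:::dataset_slice(
    ds, which(as.character(ds$data$smoker) == "no"))
  msub <- fit_copula(sub)
  samp <- sample_copula(msub, 200, seed = 1)
  expect_true(all(samp$data$pack_years == 0))
  expect_true(all(as.character(samp$data$smoker) == "no"))
})

test_that("single categorical frequencies map to [0,0.7),[0.7,1] intervals", {
  schema <- tabular_schema(
    list(col_schema("y", "categorical", c("a", "b"), role = "target"),
         col_schema("g", "categorical", c("yes", "no"))))
  df <- data.frame(y = rep(c("a", "b"), 5),
                   g = c(rep("yes", 7), rep("no", 3)))
  model <- fit_copula(tabular_dataset(df, schema))
  expect_equal(model$marginals$g$probs, c(0.7, 0.3))
  expect_equal(model$marginals$g$cum, c(0.7, 1))
})

test_that("copula recovers rank dependence of a correlated pair", {
  set.seed(31)
  n <- 5000
  x <- rnorm(n)
  y <- 0.9 * x + sqrt(1 - 0.9^2) * rnorm(n)
  schema <- tabular_schema(
    list(col_schema("cls", "categorical", c("a", "b"), role = "target"),
         col_schema("x", "numeric"), col_schema("y", "numeric")))
  df <- data.frame(cls = rep(c("a", "b"), n / 2), x = x, y = y)
  ds <- tabular_dataset(df, schema)
  model <- fit_copula(ds)
  expect_equal(model$dependence["x", "y"],
               cor(x, y, method = "spearman"), tolerance = 0.05)

  samp <- sample_copula(model, 5000, seed = 8)
  sp_train <- cor(x, y, method = "spearman")
  sp_samp <- cor(samp$data$x, samp$data$y, method = "spearman")
  expect_lt(abs(sp_train - sp_samp), 0.05)

  # marginal recovery: KS and TVD within sampling error
  expect_lte(kss(ds$data$x, samp$data$x), 0.05)
  expect_lte(tvd(ds$data$cls, samp$data$cls), 0.05)

  # samples confined to the training range
  expect_gte(min(samp$data$x), min(x))
  expect_lte(max(samp$data$x), max(x))
})

test_that("the independence baseline destroys correlation but keeps
           marginal frequencies", {
  set.seed(13)
  n <- 3000
  x <- rnorm(n)
  schema <- tabular_schema(
    list(col_schema("cls", "categorical", c("a", "b"), role = "target"),
         col_schema("x", "numeric"), col_schema("y", "numeric")))
  df <- data.frame(cls = sample(c("a", "b"), n, TRUE, c(0.3, 0.7)),
                   x = x, y = x)  # perfectly correlated pair
  ds <- tabular_dataset(df, schema)
  model <- fit_independent(ds)
  samp <- sample_independent(model, 5000, seed = 2)
  expect_lt(abs(cor(samp$data$x, samp$data$y)), 0.05)

  # chi-square goodness of fit of the categorical marginal vs training
  obs <- table(samp$data$cls)
  p_train <- as.numeric(table(ds$data$cls)) / n
  expect_gt(suppressWarnings(chisq.test(obs, p = p_train)$p.value), 1e-4)
})

test_that("sampling is deterministic in the seed and n = 0 is an empty
           table with the schema intact", {
  model <- fit_copula(toy_dataset(6L))
  a <- sample_copula(model, 50, seed = 99)
  b <- sample_copula(model, 50, seed = 99)
  expect_identical(a$data, b$data)
  z <- sample_copula(model, 0, seed = 1)
  expect_equal(n_rows(z), 0L)
  expect_equal(names(z$data), names(a$data))
})

test_that("rejection sampling hits the enumerated acceptance probability on
           the uniform 4-cell toy and returns zero violations", {
  model <- uniform_cell_model()
  rules <- list(logical_rule("smoker", "no", "pack_cat", "0"))
  # P(violate) = P(smoker = no) * P(pack_cat = 10) = 1/4 => acceptance 3/4
  samp <- rejection_sample(model, rules, 4000, seed = 21, max_batches = 10)
  expect_equal(n_rows(samp), 4000L)
  expect_equal(violation_report(samp, rules)$violation_rate, 0)
  expect_equal(attr(samp, "acceptance_rate"), 0.75, tolerance = 0.02)

  # no rules: everything accepted
  all_ok <- rejection_sample(model, list(), 100, seed = 3)
  expect_equal(attr(all_ok, "acceptance_rate"), 1)

  # unsatisfiable rule set (every smoker state constrained to an
  # out-of-support value): error naming the acceptance rate
  bad <- list(logical_rule("smoker", "no", "pack_cat", "nonexistent"),
              logical_rule("smoker", "yes", "pack_cat", "nonexistent"))
  expect_error(rejection_sample(model, bad, 50, seed = 1, max_batches = 3),
               "over-constrained")
})

test_that("volume allocation follows the stated rounding rules and
           conserves the total", {
  fx <- generate_fixture(fixture_params(n = 600, seed = 10))
  fit <- dc_synth(fx$data, min_subset_size = 10L)

  plan <- allocate_volumes(fit$partition, 5000, c(1, 1))
  expect_equal(unname(sort(plan$class_totals)), c(2500, 2500))
  expect_equal(sum(plan$per_subset), 5000L)

  plan2 <- allocate_volumes(fit$partition, 5000, c(1, 100))
  expect_equal(unname(plan2$class_totals["death"]), 50)  # round(5000/101)
  expect_equal(unname(plan2$class_totals["survival"]), 4950)
  expect_equal(sum(plan2$per_subset), 5000L)

  # proportional within-class split: subsets 300/100 share 1000 as 750/250
  expect_equal(dcsynth:::largest_remainder(1000, c(300, 100)), c(750L, 250L))
})

test_that("conquer concatenates, shuffles reproducibly, and rejects
           mismatched schemas", {
  model <- fit_copula(toy_dataset(6L))
  a <- sample_copula(model, 30, seed = 1)
  b <- sample_copula(model, 20, seed = 2)
  out <- conquer(list(a, b), seed = 5)
  expect_equal(n_rows(out), 50L)
  expect_equal(sort(row_keys(out)), sort(c(row_keys(a), row_keys(b))))
  expect_identical(conquer(list(a, b), seed = 5)$data, out$data)
  expect_error(conquer(list()), "at least one")

  other <- sample_copula(fit_copula(random_dataset(10L)), 5, seed = 1)
  expect_error(conquer(list(a, other), seed = 1), "schemas")
})

test_that("end-to-end strategies: dc is violation-free with exact class
           counts, none leaks impossible records, cs filters them", {
  fx <- generate_fixture(fixture_params(n = 800, seed = 12))
  rules <- fx$rules

  dc <- generate_std(fx$data, strategy = "dc", total = 1000, seed = 3)
  expect_equal(n_rows(dc), 1000L)
  expect_equal(violation_report(dc, rules)$violation_rate, 0)
  expect_equal(as.integer(table(dc$data$adverse_event)), c(500L, 500L))

  none <- generate_std(fx$data, strategy = "none", total = 1000, seed = 3)
  expect_gt(violation_report(none, rules)$violation_rate, 0)

  cs <- generate_std(fx$data, strategy = "cs", total = 1000, seed = 3)
  expect_equal(violation_report(cs, rules)$violation_rate, 0)

  # identical seeds give identical end-to-end output
  dc2 <- generate_std(fx$data, strategy = "dc", total = 1000, seed = 3)
  expect_identical(dc$data, dc2$data)
})

test_that("simulate.dc_synth honours imbalanced ratios", {
  fx <- generate_fixture(fixture_params(n = 800, seed = 12))
  fit <- dc_synth(fx$data)
  syn <- simulate(fit, nsim = 1010, seed = 4, class_ratio = c(1, 100))
  tab <- table(syn$data$adverse_event)
  expect_equal(unname(tab["death"]), 10)  # round(1010/101)
  expect_equal(n_rows(syn), 1010L)
})

test_that("a custom backend plugs into the contract", {
  # trivial bootstrap backend: resample training rows
  boot <- list(
    name = "bootstrap",
    fit = function(ds) ds,
    sample = function(model, n) {
      dcsynth:::dataset_slice(model, sample.int(n_rows(model), n, TRUE))
    })
  fx <- generate_fixture(fixture_params(n = 400, seed = 1))
  syn <- generate_std(fx$data, strategy = "dc", backend = boot, total = 400,
                      seed = 2)
  expect_equal(n_rows(syn), 400L)
  expect_equal(violation_report(syn, fx$rules)$violation_rate, 0)
})
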