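test_that("kss reproduces hand-derivable distances", {
  expect_equal(kss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(kss(c(0, 0), c(1, 1)), 1)
  expect_equal(kss(c(1, 2, 3, 4), c(3, 4, 5, 6)), 0.5)
  expect_error(kss(numeric(0), 1), "non-empty")
})

test_that("tvd reproduces hand-derivable distances", {
  expect_equal(tvd(c("a", "b"), c("a", "b")), 0)
  expect_equal(tvd(c("a", "a"), c("b", "b")), 1)
  expect_equal(tvd(rep(c("a", "b"), 5), c(rep("a", 3), rep("b", 7))), 0.2)
})

test_that("correlation similarity maps rho gaps onto [0, 1]", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlation_similarity(x, x, x, x), 1)
  expect_equal(correlation_similarity(x, x, x, -x), 0)
  # oracle-computed correlations 0.8 vs 0.4 -> 0.8
  set.seed(1)
  make_pair <- function(rho, n = 20000) {
    a <- rnorm(n); b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
    list(a, b)
  }
  r <- make_pair(0.8); s <- make_pair(0.4)
  expect_equal(correlation_similarity(r[[1]], r[[2]], s[[1]], s[[2]]),
               1 - abs(cor(r[[1]], r[[2]]) - cor(s[[1]], s[[2]])) / 2)
  expect_error(correlation_similarity(x, rep(1, 5), x, x), "constant")
})

test_that("contingency similarity reproduces the half-L1 joint example", {
  # real joint (0.5, 0, 0, 0.5) vs uniform (0.25 x 4) -> 0.5
  rx <- rep(c("a", "b"), each = 2)
  ry <- rep(c("x", "y"), each = 2)
  sx <- c("a", "a", "b", "b")
  sy <- c("x", "y", "x", "y")
  expect_equal(contingency_similarity(rx, ry, sx, sy), 0.5)
  expect_equal(contingency_similarity(rx, ry, rx, ry), 1)
  expect_equal(contingency_similarity(c("a"), c("x"), c("b"), c("y")), 0)
})

test_that("metrics agree with brute-force oracles on random instances", {
  set.seed(99)
  for (i in 1:60) {
    a <- sample(0:8, sample(5:40, 1), replace = TRUE) + rnorm(1)
    b <- sample(0:8, sample(5:40, 1), replace = TRUE) + rnorm(1)
    expect_equal(kss(a, b), oracle_kss(a, b), tolerance = 1e-12)

    ca <- sample(letters[1:5], sample(5:40, 1), replace = TRUE)
    cb <- sample(letters[2:6], sample(5:40, 1), replace = TRUE)
    expect_equal(tvd(ca, cb), oracle_tvd(ca, cb), tolerance = 1e-12)

    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    rx <- sample(letters[1:3], n1, TRUE); ry <- sample(c("u", "v"), n1, TRUE)
    sx <- sample(letters[1:3], n2, TRUE); sy <- sample(c("u", "v"), n2, TRUE)
    expect_equal(contingency_similarity(rx, ry, sx, sy),
                 oracle_contingency_sim(rx, ry, sx, sy), tolerance = 1e-12)
  }
})

test_that("metrics are symmetric in real vs synthetic and row-order
           invariant", {
  set.seed(17)
  a <- rnorm(50); b <- rnorm(70)
  expect_equal(kss(a, b), kss(b, a))
  ca <- sample(letters[1:4], 50, TRUE); cb <- sample(letters[1:4], 70, TRUE)
  expect_equal(tvd(ca, cb), tvd(cb, ca))
  expect_equal(kss(a, b), kss(sample(a), b))
  expect_equal(tvd(ca, cb), tvd(sample(ca), cb))
})

test_that("quality_report scores identity at exactly 1 and averages as
           stated", {
  fx <- generate_fixture(fixture_params(n = 400, seed = 20))
  rep_id <- quality_report(fx$data, fx$data)
  expect_equal(rep_id$shape, 1)
  expect_equal(rep_id$pair_trend, 1)
  expect_equal(rep_id$overall, 1)
  expect_true(all(rep_id$column_scores == 1))
  expect_true(all(rep_id$pair_scores == 1))

  # aggregate arithmetic: shape mean of columns, overall mean of the two
  expect_equal(rep_id$overall, mean(c(rep_id$shape, rep_id$pair_trend)))
  expect_equal(mean(c(0.9, 0.8)), 0.85)  # documented aggregation example
})

test_that("subsampled real data converge to overall fidelity 1", {
  fx <- generate_fixture(fixture_params(n = 5000, seed = 23))
  idx <- with(list(), {set.seed(1); sample.int(5000, 2500)})
  sub <- dcsynth:::dataset_slice(fx$data, idx)
  expect_gte(quality_report(fx$data, sub)$overall, 0.95)
})

test_that("violation_report counts impossible records and tolerates
           numeric noise below 1e-9", {
  sch <- toy_schema()
  df <- data.frame(outcome = c("death", "death", "survival", "survival"),
                   smoker = c("no", "yes", "no", "no"),
                   pack_years = c(12, 30, 0, 1e-12))
  ds <- tabular_dataset(df, sch)
  vr <- violation_report(ds, sch$rules)
  expect_equal(vr$violation_rate, 0.25)
  expect_equal(unname(vr$violations_per_rule[1]), 1L)
  expect_equal(violation_report(ds, list())$violation_rate, 0)

  bad_rule <- list(logical_rule("smoker", "no", "pack_years", 0))
  df$pack_years[4] <- 5
  expect_equal(
    violation_report(tabular_dataset(df, sch), bad_rule)$violation_rate, 0.5)
})
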