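test_that("chi-square matches hand-derivable tables", {
  expect_equal(chi_square_statistic(matrix(c(5, 5, 5, 5), 2)), 0)
  # perfect 2x2 association: chi2 = N
  expect_equal(chi_square_statistic(matrix(c(10, 0, 0, 10), 2)), 20)
  # 2x2 closed form N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) = 50*375^2/390625
  expect_equal(chi_square_statistic(matrix(c(20, 5, 5, 20), 2)), 18)
  expect_error(chi_square_statistic(matrix(0, 2, 2)), "empty")
})

test_that("cramers_v reproduces its anchor values", {
  expect_equal(cramers_v(matrix(c(10, 0, 0, 10), 2)), 1)
  expect_equal(cramers_v(matrix(c(5, 5, 5, 5), 2)), 0)
  expect_equal(cramers_v(matrix(c(20, 5, 5, 20), 2)), 0.6)
  # single observed category: no measurable association
  expect_equal(cramers_v(matrix(c(7, 3), 1, 2)), 0)
})

test_that("cramers_v agrees with the brute-force oracle on random tables", {
  set.seed(42)
  for (i in 1:80) {
    m <- random_table()
    expect_equal(cramers_v(m), oracle_cramers_v(m), tolerance = 1e-12)
  }
})

test_that("V is invariant under permutation and under duplication of data", {
  set.seed(7)
  for (i in 1:20) {
    m <- random_table()
    v <- cramers_v(m)
    expect_equal(cramers_v(m[sample(nrow(m)), sample(ncol(m))]), v,
                 tolerance = 1e-12)
    expect_equal(cramers_v(2 * m), v, tolerance = 1e-12)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("V = 1 exactly for permutation-pattern tables", {
  set.seed(11)
  for (i in 1:20) {
    r <- sample(2:5, 1)
    c <- sample(r:6, 1)
    m <- matrix(0, r, c)
    rows <- sample(rep(seq_len(r), length.out = c))
    for (j in seq_len(c)) m[rows[j], j] <- sample(1:20, 1)
    expect_equal(cramers_v(m), 1)
  }
})

test_that("discretization carves out point masses and respects quantiles", {
  x <- c(0, 0, 0, 0, 12, 30, 45, 60)
  f <- discretize_numeric(x, 4)
  expect_equal(as.character(f)[1:4], rep("0", 4))
  expect_false(any(as.character(f)[5:8] == "0"))

  # strictly increasing values split into equal quantile bins
  f2 <- discretize_numeric(seq_len(100), 4)
  expect_equal(as.integer(table(f2)), rep(25L, 4))

  # constant column: a single bin, not an error
  f3 <- discretize_numeric(rep(3.5, 10), 4)
  expect_equal(nlevels(droplevels(f3)), 1L)

  expect_error(discretize_numeric(1:10, 1), "n_bins")
})

test_that("contingency_table drops empty categories and counts correctly", {
  ds <- toy_dataset(5L)
  tab <- contingency_table(ds, "outcome", "smoker")
  expect_equal(tab$N, 20)
  expect_equal(dim(tab$counts), c(2L, 2L))
  expect_true(all(tab$counts == 5))
  expect_error(contingency_table(ds, "outcome", "pack_years"), "discretize")
})

test_that("the association matrix is symmetric with unit diagonal and finds
           the planted perfect pair", {
  fx <- generate_fixture(fixture_params(n = 800, seed = 3))
  vm <- cramers_v_matrix(fx$data)
  expect_equal(unclass(vm), t(unclass(vm)))
  expect_equal(unname(diag(vm)), rep(1, ncol(vm)))
  expect_true(all(vm >= 0 & vm <= 1))
  expect_equal(vm["smoker", "pack_years"], 1)

  pairs <- find_division_pairs(vm, target = "adverse_event")
  expect_equal(nrow(pairs), 1L)
  expect_setequal(c(pairs$col_a, pairs$col_b), c("smoker", "pack_years"))
})

test_that("independent columns score near zero and yield no division pairs", {
  set.seed(5)
  n <- 4000
  schema <- tabular_schema(
    list(col_schema("y", "categorical", c("a", "b"), role = "target"),
         col_schema("u", "categorical", c("p", "q")),
         col_schema("v", "numeric")))
  df <- data.frame(y = sample(c("a", "b"), n, TRUE),
                   u = sample(c("p", "q"), n, TRUE),
                   v = rnorm(n))
  vm <- cramers_v_matrix(tabular_dataset(df, schema))
  off <- vm[upper.tri(vm)]
  expect_true(all(off < 0.1))
  expect_equal(nrow(find_division_pairs(vm, target = "y")), 0L)
})

test_that("find_division_pairs validates its threshold", {
  vm <- cramers_v_matrix(toy_dataset(5L))
  expect_error(find_division_pairs(vm, threshold = 0), "\\(0, 1\\]")
  expect_error(find_division_pairs(vm, threshold = 1.5), "\\(0, 1\\]")
})
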