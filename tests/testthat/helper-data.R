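# Small in-code datasets used across test files.

# minimal two-feature clinical table with the smoker/pack-years rule
toy_schema <- function() {
  tabular_schema(
    list(col_schema("outcome", "categorical", c("survival", "death"),
                    role = "target"),
         col_schema("smoker", "categorical", c("no", "yes")),
         col_schema("pack_years", "numeric")),
    rules = list(logical_rule("smoker", "no", "pack_years", 0)))
}

toy_dataset <- function(n_per_cell = 5L) {
  cells <- expand.grid(outcome = c("survival", "death"),
                       smoker = c("no", "yes"),
                       stringsAsFactors = FALSE)
  df <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ]
  df$pack_years <- 0
  df$pack_years[df$smoker == "yes"] <- rep(seq_len(n_per_cell) * 10, 2)
  rownames(df) <- NULL
  tabular_dataset(df, toy_schema())
}

# schema-free random valid dataset for round-trip properties
random_dataset <- function(n = 20L, seed = 1L) {
  set.seed(seed)
  schema <- tabular_schema(
    list(col_schema("y", "categorical", c("a", "b"), role = "target"),
         col_schema("g", "categorical", c("x", "y", "z")),
         col_schema("v", "numeric"),
         col_schema("w", "numeric")),
    rules = list())
  df <- data.frame(
    y = sample(c("a", "b"), n, replace = TRUE),
    g = sample(c("x", "y", "z"), n, replace = TRUE),
    v = round(rnorm(n, 10, 3), 6),
    w = rnorm(n) * 10^sample(-3:3, n, replace = TRUE),
    stringsAsFactors = FALSE)
  # both target classes must be present for split-based tests
  df$y[1:2] <- c("a", "b")
  tabular_dataset(df, schema)
}

# canonical row strings for multiset row-equality checks
row_keys <- function(ds) {
  df <- as.data.frame(ds)
  do.call(paste, c(lapply(df, as.character), sep = "|"))
}

# 4-cell uniform toy generator for exact rejection-sampling probabilities:
# smoker x pack-years-category, independent, all cells equiprobable
uniform_cell_model <- function() {
  schema <- tabular_schema(
    list(col_schema("y", "categorical", c("a", "b"), role = "target"),
         col_schema("smoker", "categorical", c("no", "yes")),
         col_schema("pack_cat", "categorical", c("0", "10"))),
    rules = list())
  df <- expand.grid(y = c("a", "b"), smoker = c("no", "yes"),
                    pack_cat = c("0", "10"), stringsAsFactors = FALSE)
  fit_independent(tabular_dataset(df, schema))
}
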