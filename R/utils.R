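# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded package functions never perturb user code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # force creation so we can restore something
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent prefix-free, sprintf-style message
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x > 0 && x < 1
}

# population standard deviation (n divisor)
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# largest-remainder apportionment of `total` along nonnegative weights
largest_remainder <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  if (sum(weights) == 0) {
    abort("cannot apportion %d rows over all-zero weights", total)
  }
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
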