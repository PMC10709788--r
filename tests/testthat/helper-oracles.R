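# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (explicit loops, no shared code with the
# package internals) so they can arbitrate the implementation.

# Cramer V via cell-by-cell expected counts
oracle_cramers_v <- function(counts) {
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  r <- nrow(counts); c <- ncol(counts); N <- sum(counts)
  if (r < 2 || c < 2) return(0)
  chi2 <- 0
  for (i in seq_len(r)) {
    for (j in seq_len(c)) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / N
      chi2 <- chi2 + (counts[i, j] - e)^2 / e
    }
  }
  min(1, sqrt(chi2 / (N * min(r - 1, c - 1))))
}

# KS statistic by evaluating both ECDFs at every pooled point
oracle_kss <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  d <- 0
  for (t in pts) {
    d <- max(d, abs(mean(a <= t) - mean(b <= t)))
  }
  d
}

# half-L1 distance between empirical PMFs
oracle_tvd <- function(a, b) {
  cats <- union(a, b)
  s <- 0
  for (cc in cats) {
    s <- s + abs(mean(a == cc) - mean(b == cc))
  }
  s / 2
}

# contingency similarity by looping over joint cells
oracle_contingency_sim <- function(rx, ry, sx, sy) {
  cells <- union(paste(rx, ry), paste(sx, sy))
  s <- 0
  for (cc in cells) {
    s <- s + abs(mean(paste(rx, ry) == cc) - mean(paste(sx, sy) == cc))
  }
  1 - s / 2
}

# AUC by explicit pair counting, ties worth 1/2
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos) * length(neg))
}

# random contingency table with nonzero marginals
random_table <- function(max_dim = 6L) {
  repeat {
    r <- sample(2:max_dim, 1)
    c <- sample(2:max_dim, 1)
    m <- matrix(rpois(r * c, lambda = 5), r, c)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
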