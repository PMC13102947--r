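# Vectorized two-sided Wilcoxon rank-sum screen over matrix columns.
# Tie-corrected normal approximation with continuity correction, matching
# stats::wilcox.test(exact = FALSE, correct = TRUE). Used for per-gene
# screens where thousands of tests make the single-pair path too slow.
.rank_sum_matrix <- function(X, in_group) {
  X <- as.matrix(X)
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  n <- n1 + n2
  stopifnot(n == nrow(X), n1 > 0, n2 > 0)
  p <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    r <- rank(x)
    stat <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    tl <- rle(sort(x))$lengths
    ties <- sum(tl^3 - tl)
    sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - ties / (n * (n - 1))))
    z <- stat - n1 * n2 / 2
    if (sigma == 0) { p[j] <- 1; next }
    z <- (z - sign(z) * 0.5) / sigma
    p[j] <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  }
  p
}

# log2 fold change of group means on the depth-normalized (expm1) scale,
# pseudocount 1 — the single-cell DE convention
.log2_fc <- function(X, in_group) {
  m1 <- Matrix::colMeans(expm1(X[in_group, , drop = FALSE]))
  m2 <- Matrix::colMeans(expm1(X[!in_group, , drop = FALSE]))
  log2(m1 + 1) - log2(m2 + 1)
}
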