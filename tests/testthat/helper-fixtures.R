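# shared fixture builders and independent oracles

# reduced-size simulation for unit tests (same structure as the default
# small config, fewer cells per condition)
tiny_config <- function(n_per_condition = 400L, seed = 1L, ...) {
  cfg <- islet_sim_config("small", seed = seed)
  comp <- cfg$cells_per_type / sum(cfg$cells_per_type)
  over <- list(...)
  over$cells_per_type <- stats::setNames(
    isletid:::.apportion(comp, n_per_condition), names(cfg$cells_per_type))
  do.call(islet_sim_config, c(list(scale = "small", seed = seed), over))
}

# independent brute-force maximum-correlation classifier: explicit loops,
# tie rule = smallest mixture order then lexicographic label
brute_force_classify <- function(scaled, cset) {
  X <- as.matrix(scaled[, cset$features, drop = FALSE])
  C <- cset$centroids[, cset$features, drop = FALSE]
  labels <- rownames(C)
  ord <- cset$order[labels]
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    best <- NA_character_; best_r <- -Inf
    for (l in labels[order(ord, labels)]) {
      r <- suppressWarnings(cor(X[i, ], C[l, ]))
      if (!is.na(r) && r > best_r + 1e-15) { best_r <- r; best <- l }
    }
    out[i] <- best
  }
  out
}

# independent Holm step-down oracle: sort, multiply by m - i + 1, running max
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent exact two-sided Wilcoxon oracle by enumeration of all
# choose(n+m, n) group assignments of the (mid)ranks
wilcoxon_enum_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(n)])
  combos <- utils::combn(n + m, n)
  sums <- colSums(matrix(r[combos], nrow = n))
  mu <- n * sum(r) / (n + m)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# adjusted Rand index between two partitions
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# sparse matrix with an exact number of detected features / mito fraction
# per cell, for QC boundary fixtures
qc_boundary_matrix <- function(spec_rows, n_genes = 6100L, n_mito = 10L) {
  genes <- c(sprintf("G%05d", seq_len(n_genes - n_mito)), sprintf("mt-%02d", seq_len(n_mito)))
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (r in seq_along(spec_rows)) {
    s <- spec_rows[[r]]
    n_feat <- s$n_features
    mito_counts <- s$mito_counts %||% 0
    nm <- n_feat - (if (mito_counts > 0) 1L else 0L)
    cols <- seq_len(nm)
    vals <- rep(1, nm)
    if (mito_counts > 0) { cols <- c(cols, n_genes - n_mito + 1L); vals <- c(vals, mito_counts) }
    i <- c(i, rep(r, length(cols))); j <- c(j, cols); x <- c(x, vals)
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(length(spec_rows), n_genes))
  rownames(m) <- sprintf("cell-%03d", seq_along(spec_rows))
  colnames(m) <- genes
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
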