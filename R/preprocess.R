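#' QC parameters
#'
#' Defaults are the published gates: cells are kept when they have more than
#' 2500 but fewer than 6000 detected features and a mitochondrial read
#' fraction below 10%. All bounds are strict; boundary cells are removed.
#' Synthetic panels with far fewer genes should scale `min_features` /
#' `max_features` accordingly (see the simulator's `qc_defaults`).
#'
#' @param min_features Exclusive lower bound on detected features.
#' @param max_features Exclusive upper bound on detected features.
#' @param max_mito_fraction Exclusive upper bound on mitochondrial fraction.
#' @param mito_prefix Gene-symbol prefix identifying mitochondrial genes.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_features = 2500L, max_features = 6000L,
                      max_mito_fraction = 0.1, mito_prefix = "mt-") {
  if (!(min_features >= 0 && min_features < max_features))
    .stopf("need 0 <= min_features < max_features")
  if (!(max_mito_fraction > 0 && max_mito_fraction <= 1))
    .stopf("max_mito_fraction must lie in (0, 1]")
  structure(list(min_features = min_features, max_features = max_features,
                 max_mito_fraction = max_mito_fraction, mito_prefix = mito_prefix),
            class = "qc_params")
}

#' Filter cells on QC gates
#'
#' Computes per-cell metrics (detected features, total counts, mitochondrial
#' fraction) for every input cell and retains cells satisfying
#' `min_features < n_features < max_features` and
#' `mito_fraction < max_mito_fraction` (all strict). Removal reasons are
#' recorded per cell.
#'
#' @param counts Sparse or dense cells x genes count matrix with gene symbols
#'   as column names and barcodes as row names.
#' @param params A [qc_params()].
#' @return List with `counts` (retained cells) and `cell_table`, a
#'   `data.frame` over all input cells with columns `barcode`, `n_features`,
#'   `total_counts`, `mito_fraction`, `qc_pass`, `removal_reason`.
#' @export
qc_filter <- function(counts, params = qc_params()) {
  if (is.null(colnames(counts))) .stopf("counts must carry gene symbols as colnames")
  if (is.null(rownames(counts))) .stopf("counts must carry barcodes as rownames")
  n_features <- Matrix::rowSums(counts > 0)
  total <- Matrix::rowSums(counts)
  is_mt <- startsWith(colnames(counts), params$mito_prefix)
  mito_total <- if (any(is_mt)) Matrix::rowSums(counts[, is_mt, drop = FALSE]) else rep(0, nrow(counts))
  mito_fraction <- ifelse(total > 0, mito_total / total, 0)

  low <- n_features <= params$min_features
  high <- n_features >= params$max_features
  mito_bad <- mito_fraction >= params$max_mito_fraction
  pass <- !(low | high | mito_bad)
  reason <- vapply(seq_along(pass), function(i) {
    paste(c(if (low[i]) "low_features", if (high[i]) "high_features",
            if (mito_bad[i]) "high_mito"), collapse = ",")
  }, character(1))

  tab <- data.frame(barcode = rownames(counts),
                    n_features = as.integer(n_features),
                    total_counts = as.numeric(total),
                    mito_fraction = as.numeric(mito_fraction),
                    qc_pass = pass,
                    removal_reason = reason,
                    stringsAsFactors = FALSE)
  if (!any(pass))
    .stopf("QC removed all %d cells; override qc_params() thresholds for this panel",
           nrow(counts))
  list(counts = counts[pass, , drop = FALSE], cell_table = tab)
}

#' Log-normalize counts to a common depth
#'
#' `value = log(1 + scale_total * count / cell_total)`, the standard
#' log-normalization the marker gates are defined on. Cells with zero total
#' counts are flagged (attribute `zero_total_cells`) and left at zero rather
#' than divided.
#'
#' @param counts Cells x genes count matrix (sparse supported).
#' @param scale_total Target depth (default 1e4).
#' @return Sparse cells x genes matrix of normalized values.
#' @export
normalize_log <- function(counts, scale_total = 1e4) {
  if (any(counts < 0)) .stopf("counts must be nonnegative")
  total <- Matrix::rowSums(counts)
  zero <- total == 0
  fac <- ifelse(zero, 0, scale_total / total)
  norm <- Matrix::Diagonal(x = fac) %*% counts
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  if (any(zero)) attr(norm, "zero_total_cells") <- rownames(counts)[zero]
  norm
}

#' Z-score genes across cells with clipping
#'
#' Centers and scales each gene to mean 0 and unit sample standard deviation
#' across cells, then clips to `[-clip, clip]` to bound outlier leverage on
#' centroids. Zero-variance genes are set to 0.
#'
#' @param norm Cells x genes normalized matrix.
#' @param clip Symmetric clip bound (default 10).
#' @return Dense cells x genes matrix of scaled values.
#' @export
scale_genes <- function(norm, clip = 10) {
  m <- as.matrix(norm)
  sc <- scale(m)                      # sample-sd convention (n - 1)
  sc[, attr(sc, "scaled:scale") == 0] <- 0
  sc[is.na(sc)] <- 0
  sc <- pmin(pmax(sc, -clip), clip)
  attr(sc, "scaled:center") <- NULL
  attr(sc, "scaled:scale") <- NULL
  dimnames(sc) <- dimnames(norm)
  sc
}

#' Clustering parameters
#'
#' Defaults follow the published settings: 30 principal components and
#' shared-nearest-neighbor modularity clustering at resolution 2.
#'
#' @param n_pcs Number of principal components (>= 2).
#' @param k_neighbors Neighborhood size of the kNN graph.
#' @param resolution Modularity resolution (> 0).
#' @param seed Integer seed for the community detection.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(n_pcs = 30L, k_neighbors = 20L, resolution = 2,
                           seed = 1L) {
  if (n_pcs < 2) .stopf("n_pcs must be >= 2")
  if (resolution <= 0) .stopf("resolution must be > 0")
  structure(list(n_pcs = as.integer(n_pcs), k_neighbors = as.integer(k_neighbors),
                 resolution = resolution, seed = as.integer(seed)),
            class = "cluster_params")
}

# k nearest neighbor indices (excluding self), blockwise to bound memory
.knn_index <- function(x, k) {
  n <- nrow(x)
  nn <- matrix(0L, n, k)
  block <- 2000L
  sq <- rowSums(x^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * x[idx, , drop = FALSE] %*% t(x)
    for (j in seq_along(idx)) {
      d2[j, idx[j]] <- Inf
      nn[idx[j], ] <- order(d2[j, ])[seq_len(k)]
    }
  }
  nn
}

#' Graph-based clustering of scaled expression
#'
#' PCA to `n_pcs`, a kNN graph, shared-nearest-neighbor (Jaccard) weighting
#' with pruning, and modularity community detection (Louvain) at the given
#' resolution. Deterministic given the seed; labels are contiguous integers
#' starting at 1 (arbitrary identity, compare partitions not labels).
#'
#' @param scaled Cells x genes scaled matrix.
#' @param params A [cluster_params()].
#' @return Integer vector of cluster labels named by barcode.
#' @export
cluster_graph <- function(scaled, params = cluster_params()) {
  n <- nrow(scaled)
  if (n <= params$k_neighbors)
    .stopf("need more than k_neighbors = %d cells, got %d", params$k_neighbors, n)
  set.seed(params$seed)
  n_pcs <- min(params$n_pcs, n - 1L, ncol(scaled))
  pcs <- stats::prcomp(scaled, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  if (all(abs(pcs) < 1e-10)) {            # identical cells: one community
    return(stats::setNames(rep(1L, n), rownames(scaled)))
  }
  k <- params$k_neighbors
  nn <- .knn_index(pcs, k)

  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nn)),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)            # shared neighbor counts
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)             # Jaccard on k-sets
  jac@x[jac@x < 1 / 15] <- 0                   # prune weak links
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  if (igraph::ecount(g) == 0) {
    labels <- rep(1L, n)
  } else {
    comm <- igraph::cluster_louvain(g, resolution = params$resolution)
    labels <- as.integer(igraph::membership(comm))
    labels <- as.integer(factor(labels, levels = unique(labels)))
  }
  names(labels) <- rownames(scaled)
  labels
}
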