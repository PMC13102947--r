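#' Gate cells on canonical marker thresholds
#'
#' Extracts each panel marker from the log-normalized matrix and applies its
#' threshold with a strict `>` comparison. Cells exceeding exactly one
#' marker's threshold are pure-profile cells of that marker's type; cells
#' exceeding two or more are mixed candidates; cells exceeding none are
#' unassigned.
#'
#' @param norm Cells x genes log-normalized matrix.
#' @param panel A [marker_panel()].
#' @return `data.frame` with `barcode`, `markers_above` (comma-joined),
#'   `n_markers`, `status` (`pure` / `candidate_mixed` / `unassigned`) and
#'   `gate_type` (the type for pure cells, `NA` otherwise).
#' @export
gate_cells <- function(norm, panel = default_marker_panel()) {
  missing <- setdiff(panel$marker, colnames(norm))
  if (length(missing))
    .stopf("marker gene(s) absent from matrix: %s", paste(missing, collapse = ", "))
  vals <- as.matrix(norm[, panel$marker, drop = FALSE])
  above <- sweep(vals, 2, panel$threshold, ">")
  n_above <- rowSums(above)
  markers_above <- apply(above, 1, function(a) paste(panel$marker[a], collapse = ","))
  status <- ifelse(n_above == 0, "unassigned",
                   ifelse(n_above == 1, "pure", "candidate_mixed"))
  type_of <- stats::setNames(panel$cell_type, panel$marker)
  gate_type <- ifelse(status == "pure", type_of[markers_above], NA_character_)
  data.frame(barcode = rownames(norm), markers_above = markers_above,
             n_markers = as.integer(n_above), status = status,
             gate_type = unname(gate_type), stringsAsFactors = FALSE)
}

#' Top discriminative genes per cell type
#'
#' Within pure-profile cells only, performs a one-vs-rest differential
#' expression screen (Wilcoxon rank-sum on normalized values) for each type
#' and takes the top `k` genes ranked by p-value, then absolute log2 fold
#' change, then gene symbol. The combined feature set is the union of the
#' panel markers (first) and each type's list in type order, deduplicated.
#'
#' @param norm Cells x genes log-normalized matrix.
#' @param gate Output of [gate_cells()].
#' @param panel The marker panel used for gating.
#' @param k Genes per type (default 10; `k = 0` returns panel genes only).
#' @return List with `per_type` (named list of character vectors) and
#'   `features` (the combined feature set `F`).
#' @export
top_discriminative_genes <- function(norm, gate, panel = default_marker_panel(),
                                     k = 10L) {
  types <- unique(panel$cell_type)
  pure <- gate$status == "pure"
  counts_per_type <- table(factor(gate$gate_type[pure], levels = types))
  few <- names(counts_per_type)[counts_per_type < 3]
  if (length(few))
    .stopf("type(s) with fewer than 3 pure-profile cells: %s", paste(few, collapse = ", "))
  per_type <- stats::setNames(vector("list", length(types)), types)
  if (k > 0) {
    sub <- as.matrix(norm[pure, , drop = FALSE])
    sub_type <- gate$gate_type[pure]
    for (ty in types) {
      in_grp <- sub_type == ty
      p <- .rank_sum_matrix(sub, in_grp)
      lfc <- .log2_fc(sub, in_grp)
      # genes enriched in the type come first, then p, then effect, then symbol
      ord <- order(lfc <= 0, p, -abs(lfc), colnames(sub))
      per_type[[ty]] <- colnames(sub)[ord][seq_len(min(k, ncol(sub)))]
    }
  } else {
    per_type <- stats::setNames(rep(list(character(0)), length(types)), types)
  }
  features <- unique(c(panel$marker, unlist(per_type, use.names = FALSE)))
  list(per_type = per_type, features = features)
}

#' Build pure cell-type centroids
#'
#' The centroid of a type is the arithmetic mean of the scaled expression
#' profiles of its pure-profile cells over the discriminative feature set.
#'
#' @param scaled Cells x genes scaled matrix.
#' @param gate Output of [gate_cells()].
#' @param features Character vector of feature genes `F`.
#' @return A `centroid_set`: list with `features`, `centroids` (labels x
#'   features matrix) and `order` (1 for pure labels).
#' @export
build_centroids <- function(scaled, gate, features) {
  missing <- setdiff(features, colnames(scaled))
  if (length(missing))
    .stopf("feature gene(s) absent from scaled matrix: %s", paste(missing, collapse = ", "))
  pure <- gate$status == "pure"
  types <- sort(unique(gate$gate_type[pure]))
  if (!length(types)) .stopf("no pure-profile cells to build centroids from")
  cent <- t(vapply(types, function(ty) {
    rows <- which(pure & gate$gate_type == ty)
    if (!length(rows)) .stopf("no pure-profile cells for type %s", ty)
    colMeans(scaled[rows, features, drop = FALSE])
  }, numeric(length(features))))
  dimnames(cent) <- list(types, features)
  structure(list(features = features, centroids = cent,
                 order = stats::setNames(rep(1L, length(types)), types)),
            class = "centroid_set")
}

#' Add artificial mixed-type centroids
#'
#' For every pairwise (and, by default, triple) combination of pure types,
#' adds an artificial mixed centroid: the unweighted mean of the constituent
#' pure centroids, modeling the in-between profile a mixed or polyhormonal
#' cell is expected to show. Labels are `+`-joined sorted type tuples.
#'
#' @param cset A pure `centroid_set` from [build_centroids()].
#' @param orders Mixture orders to add (subset of `c(2, 3)`).
#' @param weights Optional mixing weights (length matching each order);
#'   default unweighted.
#' @return The extended `centroid_set` with `order` 1, 2 and 3 labels.
#' @export
build_mixed_centroids <- function(cset, orders = c(2L, 3L), weights = NULL) {
  pure_labels <- rownames(cset$centroids)[cset$order == 1L]
  if (length(pure_labels) < 3) .stopf("need >= 3 pure centroids, got %d", length(pure_labels))
  pure <- cset$centroids[pure_labels, , drop = FALSE]
  cent <- cset$centroids
  ord <- cset$order
  for (m in sort(orders)) {
    combos <- utils::combn(sort(pure_labels), m)
    w <- weights[[as.character(m)]] %||% rep(1 / m, m)
    if (length(w) != m || abs(sum(w) - 1) > 1e-8)
      .stopf("weights for order %d must have length %d and sum to 1", m, m)
    mixed <- apply(combos, 2, function(tys) colSums(pure[tys, , drop = FALSE] * w))
    mixed <- t(mixed)
    labels <- apply(combos, 2, paste, collapse = "+")
    rownames(mixed) <- labels
    cent <- rbind(cent, mixed)
    ord <- c(ord, stats::setNames(rep(as.integer(m), length(labels)), labels))
  }
  structure(list(features = cset$features, centroids = cent, order = ord),
            class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("centroid_set: %d centroids (%s) over %d features\n",
              nrow(x$centroids),
              paste(sprintf("order %d: %d", sort(unique(x$order)),
                            as.integer(table(x$order))), collapse = ", "),
              length(x$features)))
  invisible(x)
}

#' Export / import a centroid set as TSV (label x gene)
#'
#' @param cset A `centroid_set`.
#' @param path File path.
#' @return `path` invisibly (`write`), or a `centroid_set` (`read`).
#' @export
write_centroids <- function(cset, path) {
  df <- data.frame(label = rownames(cset$centroids),
                   order = unname(cset$order[rownames(cset$centroids)]),
                   as.data.frame(cset$centroids, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  df <- .read_tsv(path)
  cent <- as.matrix(df[, setdiff(names(df), c("label", "order")), drop = FALSE])
  rownames(cent) <- df$label
  structure(list(features = colnames(cent), centroids = cent,
                 order = stats::setNames(as.integer(df$order), df$label)),
            class = "centroid_set")
}

#' Classify cells by maximum correlation to centroids
#'
#' Pearson-correlates each cell's scaled profile over the feature set against
#' every (pure and mixed) centroid and assigns the label of the highest
#' correlation. Ties are broken by smallest mixture order (pure before pair
#' before triple), then lexicographically. Cells with zero variance over the
#' features have no defined correlation and are returned `unclassified`.
#' Zero-variance centroids are excluded with a warning.
#'
#' @param scaled Cells x genes scaled matrix (must contain the features).
#' @param cset A `centroid_set`.
#' @param return_correlations Also return the full cell x centroid matrix.
#' @return `data.frame` with `barcode`, `best_label`, `best_correlation`,
#'   `label_order`, `status` (`classified` / `unclassified`); optionally the
#'   correlation matrix as attribute `correlations`.
#' @export
classify_by_correlation <- function(scaled, cset, return_correlations = FALSE) {
  if (length(cset$features) < 3) .stopf("need at least 3 feature genes")
  X <- as.matrix(scaled[, cset$features, drop = FALSE])
  C <- cset$centroids[, cset$features, drop = FALSE]
  cvar <- apply(C, 1, stats::var)
  if (any(cvar == 0)) {
    .warnf("excluding %d zero-variance centroid(s): %s", sum(cvar == 0),
           paste(rownames(C)[cvar == 0], collapse = ", "))
    C <- C[cvar > 0, , drop = FALSE]
  }
  if (!nrow(C)) .stopf("all centroids have zero variance")
  ord <- cset$order[rownames(C)]
  # deterministic tie preference: smallest order, then label
  pref <- order(ord, rownames(C))
  C <- C[pref, , drop = FALSE]
  ord <- ord[pref]

  xvar <- apply(X, 1, stats::var)
  cors <- matrix(NA_real_, nrow(X), nrow(C), dimnames = list(rownames(X), rownames(C)))
  ok <- xvar > 0
  if (any(ok)) cors[ok, ] <- stats::cor(t(X[ok, , drop = FALSE]), t(C))

  best_idx <- apply(cors, 1, function(r) if (all(is.na(r))) NA_integer_ else which.max(r))
  res <- data.frame(
    barcode = rownames(X),
    best_label = ifelse(is.na(best_idx), NA_character_, rownames(C)[best_idx]),
    best_correlation = ifelse(is.na(best_idx), NA_real_,
                              cors[cbind(seq_len(nrow(X)), best_idx)]),
    label_order = ifelse(is.na(best_idx), NA_integer_, ord[best_idx]),
    status = ifelse(is.na(best_idx), "unclassified", "classified"),
    stringsAsFactors = FALSE
  )
  if (return_correlations) attr(res, "correlations") <- cors
  res
}
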