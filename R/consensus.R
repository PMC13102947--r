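#' Simulated-doublet kNN doublet detector
#'
#' Synthesizes `n_sim` artificial doublets by summing the counts of uniformly
#' sampled pairs of distinct observed cells, co-embeds observed and
#' artificial cells in a PCA of log-normalized (scaled) expression, and
#' scores each observed cell by the fraction of its `k` nearest neighbors
#' that are artificial. The top `expected_rate` quantile of scores is
#' flagged, i.e. exactly `round(expected_rate * n_cells)` cells, ties broken
#' by cell index. Deterministic given `seed`.
#'
#' With `use_depth = TRUE` (default) a standardized log10 total-UMI dimension
#' is appended to the embedding, weighted like the leading expression axis.
#' Depth is a standard doublet feature: droplets holding two cells carry
#' roughly twice the library of a singlet, which depth-free normalized
#' expression cannot see, and it is precisely what separates genuine doublets
#' from polyhormonal cells whose in-between expression profile mimics a
#' mixed droplet at singlet depth.
#'
#' @param counts Cells x genes count matrix.
#' @param expected_rate Expected doublet fraction in (0, 1).
#' @param n_sim Number of artificial doublets (default: one per observed cell).
#' @param k Neighborhood size.
#' @param n_pcs Number of principal components for the embedding.
#' @param use_depth Append the library-size dimension to the embedding.
#' @param seed Integer seed.
#' @return `data.frame` with `barcode`, `score`, `flagged`.
#' @export
detect_doublets_simulated <- function(counts, expected_rate = 0.08,
                                      n_sim = NULL, k = 30L, n_pcs = 10L,
                                      use_depth = TRUE, seed = 1L) {
  if (!(expected_rate > 0 && expected_rate < 1))
    .stopf("expected_rate must lie strictly in (0, 1)")
  n <- nrow(counts)
  if (n < 2 * k) .stopf("need at least 2 * k = %d cells, got %d", 2 * k, n)
  n_sim <- n_sim %||% n
  if (n_sim < 10 * k)
    .warnf("n_sim = %d is below 10 * k = %d; scores will be noisy", n_sim, 10 * k)
  set.seed(seed)
  i <- sample.int(n, n_sim, replace = TRUE)
  j <- sample.int(n - 1L, n_sim, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)      # distinct partner
  art <- counts[i, , drop = FALSE] + counts[j, , drop = FALSE]
  rownames(art) <- sprintf("artificial-%06d", seq_len(n_sim))
  merged <- rbind(counts, art)
  norm <- normalize_log(merged)
  sc <- scale_genes(norm)
  n_pcs <- min(n_pcs, nrow(sc) - 1L, ncol(sc))
  pcs <- stats::prcomp(sc, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  if (use_depth) {
    depth <- as.numeric(scale(log10(Matrix::rowSums(merged) + 1)))
    pcs <- cbind(pcs, depth * stats::sd(pcs[, 1]))
  }
  nn <- .knn_index(pcs, k)
  is_art <- c(rep(FALSE, n), rep(TRUE, n_sim))
  score <- rowMeans(matrix(is_art[nn[seq_len(n), ]], nrow = n))
  n_flag <- round(expected_rate * n)
  flagged <- rep(FALSE, n)
  flagged[order(-score, seq_len(n))[seq_len(n_flag)]] <- TRUE
  data.frame(barcode = rownames(counts), score = score, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Read externally produced doublet flags
#'
#' Adapter for slotting real doublet-detector outputs (e.g. DoubletFinder or
#' Scrublet calls exported as TSV) into the majority vote. Expected columns:
#' `barcode`, `flagged` (logical or 0/1), optional `score`.
#'
#' @param path TSV path.
#' @return `data.frame` with `barcode`, `score`, `flagged`.
#' @export
read_detector_flags <- function(path) {
  df <- .read_tsv(path)
  need <- c("barcode", "flagged")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("detector flag file missing columns: %s", paste(miss, collapse = ", "))
  data.frame(barcode = as.character(df$barcode),
             score = if ("score" %in% names(df)) as.numeric(df$score) else NA_real_,
             flagged = as.logical(df$flagged), stringsAsFactors = FALSE)
}

#' Majority vote over mixed-type inferences
#'
#' Combines the centroid-based mixed call with at least two doublet
#' detectors. Cells flagged by more than one approach are doublets. A single
#' vote that comes from the centroid call alone marks a suggestive
#' polyhormonal candidate; a single vote from a doublet detector alone is
#' retained as a singlet with the disagreement recorded; no votes is a
#' singlet.
#'
#' @param flags `data.frame` with a `barcode` column, a logical
#'   `centroid_mixed` column and at least two further logical detector
#'   columns (e.g. `detector_A`, `detector_B`).
#' @return `data.frame` with `barcode`, `votes`, `outcome`
#'   (`doublet` / `polyhormonal_candidate` / `singlet`) and `note`.
#' @export
majority_vote <- function(flags) {
  if (!"barcode" %in% names(flags)) .stopf("flags must carry a barcode column")
  det_cols <- setdiff(names(flags), "barcode")
  det_cols <- det_cols[vapply(flags[det_cols], is.logical, logical(1))]
  if (!"centroid_mixed" %in% det_cols)
    .stopf("flags must include a logical centroid_mixed column")
  if (length(det_cols) < 3)
    .stopf("majority vote requires >= 3 detectors, got %d", length(det_cols))
  if (anyDuplicated(flags$barcode)) .stopf("duplicated barcodes in flags")
  m <- as.matrix(flags[, det_cols, drop = FALSE])
  if (anyNA(m)) .stopf("detector flags must not contain NA (misaligned cells?)")
  votes <- rowSums(m)
  centroid <- flags$centroid_mixed
  outcome <- ifelse(votes >= 2, "doublet",
                    ifelse(votes == 1 & centroid, "polyhormonal_candidate",
                           "singlet"))
  note <- character(nrow(flags))
  note[votes == 1 & !centroid] <- "single_detector_flag"
  note[votes >= 2 & !centroid] <- "detectors_only"
  data.frame(barcode = flags$barcode, votes = as.integer(votes),
             outcome = outcome, note = note, stringsAsFactors = FALSE)
}

#' Finalize per-cell identity labels
#'
#' Merges the vote outcome with the centroid call: doublets are marked for
#' removal from downstream analyses; polyhormonal candidates keep their mixed
#' tuple label and are quantifiable only when every constituent type is
#' endocrine (mixed tuples with non-endocrine constituents are dismissed from
#' quantification); singlets keep their pure centroid label. Cells without a
#' defined centroid correlation are `unclassified`.
#'
#' @param votes Output of [majority_vote()].
#' @param calls Output of [classify_by_correlation()] (aligned barcodes).
#' @param panel The [marker_panel()] declaring which types are endocrine.
#' @return `data.frame` with `barcode`, `status`
#'   (`singlet` / `doublet` / `polyhormonal` / `unclassified`), `final_label`,
#'   `quantifiable`, `removal_reason`.
#' @export
finalize_labels <- function(votes, calls, panel = default_marker_panel()) {
  if (!identical(votes$barcode, calls$barcode))
    .stopf("votes and calls must be aligned on the same barcodes")
  endo <- .endocrine_types(panel)
  n <- nrow(votes)
  status <- character(n)
  label <- calls$best_label
  quant <- rep(TRUE, n)
  reason <- character(n)
  for (i in seq_len(n)) {
    if (calls$status[i] == "unclassified") {
      status[i] <- "unclassified"; label[i] <- NA_character_
      quant[i] <- FALSE; reason[i] <- "no_defined_correlation"
    } else if (votes$outcome[i] == "doublet") {
      status[i] <- "doublet"; quant[i] <- FALSE
      reason[i] <- if (votes$note[i] == "detectors_only") "doublet_detectors_only" else "doublet_majority_vote"
    } else if (votes$outcome[i] == "polyhormonal_candidate") {
      status[i] <- "polyhormonal"
      constituents <- strsplit(label[i], "+", fixed = TRUE)[[1]]
      quant[i] <- all(constituents %in% endo)
      if (!quant[i]) reason[i] <- "mixed_with_non_endocrine"
    } else {
      status[i] <- "singlet"
      if (calls$label_order[i] > 1) {
        # detector-only vote on a mixed centroid call cannot happen (that
        # pattern has >= 2 votes); a mixed call with zero votes is impossible
        # by construction, but guard anyway
        status[i] <- "polyhormonal"
        constituents <- strsplit(label[i], "+", fixed = TRUE)[[1]]
        quant[i] <- all(constituents %in% endo)
      }
    }
  }
  data.frame(barcode = votes$barcode, status = status, final_label = label,
             quantifiable = quant, removal_reason = reason,
             stringsAsFactors = FALSE)
}
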