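#' Run the full islet identity pipeline
#'
#' Orchestrates the stages in the order QC, normalization, clustering, marker
#' gating, discriminative-feature selection, centroid construction (pure +
#' mixed), maximum-correlation classification, doublet detection (two
#' detectors, run per condition), majority vote, label finalization,
#' composition, optional module-score group inference, and per-gene DE within
#' the target cell type. Writes seven outputs under `out_dir`:
#' `cell_table.tsv`, `centroids.tsv`, `final_status.tsv`, `composition.tsv`,
#' `group_comparison.tsv`, `de_genes.tsv` and `manifest.json` (config echo,
#' seed, package version, stage checksums). Identical input, configuration
#' and seed reproduce identical output checksums.
#'
#' All stage seeds are derived from the single `seed` argument.
#'
#' @param input Either a cells x genes count matrix (then `condition` is
#'   required) or a named list of 10x triplet directories, one per condition.
#' @param condition Per-cell condition labels (when `input` is a matrix).
#' @param panel A [marker_panel()].
#' @param qc A [qc_params()].
#' @param cluster A [cluster_params()] (its seed is overridden from `seed`).
#' @param k_top Discriminative genes per type.
#' @param mixed_orders Mixture orders for artificial centroids.
#' @param expected_doublet_rate Expected doublet fraction for the detectors.
#' @param programs Optional named list of gene programs for module scoring.
#' @param target_type Cell type for module scoring and condition DE.
#' @param de A [de_params()].
#' @param score A [score_params()] (its seed is overridden from `seed`).
#' @param out_dir Output directory (created; pass `NULL` to skip writing).
#' @param seed Integer master seed.
#' @return Invisible list with all intermediate and final tables:
#'   `cell_table`, `centroids`, `final`, `composition`, `group_comparison`,
#'   `de`, `manifest`.
#' @export
run_islet_pipeline <- function(input, condition = NULL,
                               panel = default_marker_panel(),
                               qc = qc_params(),
                               cluster = cluster_params(),
                               k_top = 10L,
                               mixed_orders = c(2L, 3L),
                               expected_doublet_rate = 0.08,
                               programs = NULL,
                               target_type = "beta",
                               de = de_params(),
                               score = score_params(),
                               out_dir = NULL,
                               seed = 1L) {
  seed <- as.integer(seed)
  if (is.list(input) && !.is_count_matrix(input)) {
    if (is.null(names(input))) .stopf("input list must be named by condition")
    mats <- lapply(input, read_10x)
    condition <- rep(names(mats), vapply(mats, nrow, integer(1)))
    counts <- do.call(rbind, mats)
  } else {
    counts <- input
    if (is.null(condition) || length(condition) != nrow(counts))
      .stopf("condition labels must be given for every cell")
  }
  condition <- as.character(condition)

  qc_res <- qc_filter(counts, qc)
  cell_table <- qc_res$cell_table
  cell_table$condition <- condition
  keep <- cell_table$qc_pass
  counts_qc <- qc_res$counts
  cond_qc <- condition[keep]

  norm <- normalize_log(counts_qc)
  scaled <- scale_genes(norm)

  cluster$seed <- seed + 303L
  clusters <- cluster_graph(scaled, cluster)

  gate <- gate_cells(norm, panel)
  feats <- top_discriminative_genes(norm, gate, panel, k = k_top)
  cset <- build_centroids(scaled, gate, feats$features)
  cset <- build_mixed_centroids(cset, orders = mixed_orders)
  calls <- classify_by_correlation(scaled, cset)

  run_detector <- function(dseed, k, n_pcs) {
    flags <- rep(NA, nrow(counts_qc))
    score_v <- rep(NA_real_, nrow(counts_qc))
    for (cn in unique(cond_qc)) {
      idx <- which(cond_qc == cn)
      det <- detect_doublets_simulated(counts_qc[idx, , drop = FALSE],
                                       expected_rate = expected_doublet_rate,
                                       k = k, n_pcs = n_pcs, seed = dseed)
      flags[idx] <- det$flagged
      score_v[idx] <- det$score
    }
    list(flagged = as.logical(flags), score = score_v)
  }
  det_a <- run_detector(seed + 101L, k = 30L, n_pcs = 10L)
  det_b <- run_detector(seed + 202L, k = 15L, n_pcs = 15L)

  flags <- data.frame(barcode = calls$barcode,
                      centroid_mixed = !is.na(calls$label_order) & calls$label_order >= 2L,
                      detector_A = det_a$flagged,
                      detector_B = det_b$flagged,
                      stringsAsFactors = FALSE)
  votes <- majority_vote(flags)
  final <- finalize_labels(votes, calls, panel)
  comp <- composition_table(final, cond_qc)

  # module scores and group inference within the target type's singlets
  group_cmp <- data.frame(program = character(0), p_raw = numeric(0),
                          p_holm = numeric(0), effect = numeric(0),
                          method = character(0), n_ref = integer(0),
                          n_alt = integer(0), stringsAsFactors = FALSE)
  if (!is.null(programs)) {
    tgt <- final$status == "singlet" & final$final_label == target_type
    if (sum(tgt) >= 4 && length(unique(cond_qc[tgt])) == 2) {
      score$seed <- seed + 404L
      smat <- vapply(programs, function(g) module_score(norm[tgt, , drop = FALSE], g, score),
                     numeric(sum(tgt)))
      group_cmp <- compare_module_scores(smat, cond_qc[tgt])
    } else {
      .warnf("too few %s singlets for group inference; skipping", target_type)
    }
  }

  de_tab <- data.frame(gene = character(0), log2_fc = numeric(0),
                       pct_ref = numeric(0), pct_alt = numeric(0),
                       p_value = numeric(0), p_adj = numeric(0),
                       significant = logical(0), stringsAsFactors = FALSE)
  tgt <- final$status == "singlet" & final$final_label == target_type
  if (min(table(factor(cond_qc[tgt], levels = unique(cond_qc)))) >= 3) {
    de_tab <- de_between_conditions(norm[tgt, , drop = FALSE], cond_qc[tgt], de)
  }

  # assemble the per-cell table over all input cells
  idx <- match(cell_table$barcode, calls$barcode)
  cell_table$cluster <- NA_integer_
  cell_table$cluster[keep] <- unname(clusters)
  cell_table$gate_status <- gate$status[idx]
  cell_table$gate_markers <- gate$markers_above[idx]
  cell_table$gate_type <- gate$gate_type[idx]
  cell_table$best_label <- calls$best_label[idx]
  cell_table$best_correlation <- calls$best_correlation[idx]
  cell_table$detector_A <- det_a$flagged[idx]
  cell_table$detector_A_score <- det_a$score[idx]
  cell_table$detector_B <- det_b$flagged[idx]
  cell_table$detector_B_score <- det_b$score[idx]
  cell_table$votes <- votes$votes[idx]
  cell_table$final_status <- final$status[idx]
  cell_table$final_label <- final$final_label[idx]
  cell_table$quantifiable <- final$quantifiable[idx]

  manifest <- list(
    package = "isletid",
    version = as.character(utils::packageVersion("isletid")),
    seed = seed,
    n_cells_input = nrow(counts),
    n_cells_qc = nrow(counts_qc),
    n_features = ncol(counts),
    n_centroids = nrow(cset$centroids),
    feature_set_size = length(cset$features),
    config = list(
      qc = unclass(qc), cluster = unclass(cluster), k_top = k_top,
      mixed_orders = mixed_orders, expected_doublet_rate = expected_doublet_rate,
      target_type = target_type, de = unclass(de),
      score = unclass(score), programs = names(programs) %||% character(0)
    )
  )

  out <- list(cell_table = cell_table, centroids = cset, calls = calls,
              final = final, composition = comp, group_comparison = group_cmp,
              de = de_tab, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(cell_table, file.path(out_dir, "cell_table.tsv"))
    write_centroids(cset, file.path(out_dir, "centroids.tsv"))
    .write_tsv(final, file.path(out_dir, "final_status.tsv"))
    .write_tsv(comp, file.path(out_dir, "composition.tsv"))
    .write_tsv(group_cmp, file.path(out_dir, "group_comparison.tsv"))
    .write_tsv(de_tab, file.path(out_dir, "de_genes.tsv"))
    files <- c("cell_table.tsv", "centroids.tsv", "final_status.tsv",
               "composition.tsv", "group_comparison.tsv", "de_genes.tsv")
    manifest$stage_checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(manifest$stage_checksums) <- files
    out$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}
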