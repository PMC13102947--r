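#' Module score parameters
#'
#' Expression-bin and control-gene counts for the signature scoring method of
#' Tirosh and colleagues (bin genes by average expression, draw control genes
#' from the program genes' bins).
#'
#' @param n_bins Number of expression bins (>= 2; default 25).
#' @param n_ctrl Control genes drawn per program gene (default 100).
#' @param seed Integer seed for the control draw.
#' @return A list of class `score_params`.
#' @export
score_params <- function(n_bins = 25L, n_ctrl = 100L, seed = 1L) {
  if (n_bins < 2) .stopf("n_bins must be >= 2")
  if (n_ctrl < 1) .stopf("n_ctrl must be >= 1")
  structure(list(n_bins = as.integer(n_bins), n_ctrl = as.integer(n_ctrl),
                 seed = as.integer(seed)), class = "score_params")
}

#' Per-cell gene-program module score
#'
#' Genes are ranked by average expression across cells and cut into `n_bins`
#' equal-size bins. For each program gene, `n_ctrl` control genes are drawn
#' from its bin (excluding all program genes; with replacement when the bin
#' is smaller than `n_ctrl`). The score of a cell is the mean normalized
#' expression over the program genes minus the mean over the pooled control
#' draw. A program gene whose bin holds no non-program genes serves as its
#' own control (so a program spanning the whole gene universe scores exactly
#' 0). Program genes absent from the matrix are dropped with a warning.
#' Binning and sampling are keyed on gene identity (candidates processed in
#' sorted order), so gene-order permutations of the matrix do not change the
#' result for a given seed.
#'
#' @param norm Cells x genes normalized matrix.
#' @param program Character vector of program genes (or a list with elements
#'   `name` and `genes`).
#' @param params A [score_params()].
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(norm, program, params = score_params()) {
  if (is.list(program)) program <- program$genes
  program <- unique(program)
  genes <- colnames(norm)
  if (length(genes) < params$n_bins)
    .stopf("matrix has %d genes but n_bins = %d", length(genes), params$n_bins)
  missing <- setdiff(program, genes)
  if (length(missing)) {
    .warnf("dropping %d program gene(s) absent from matrix", length(missing))
    program <- setdiff(program, missing)
  }
  if (!length(program)) .stopf("program empty after dropping missing genes")

  avg <- Matrix::colMeans(norm)
  ord <- order(avg, genes)                      # ties broken by symbol
  bin <- integer(length(genes))
  bin[ord] <- as.integer(cut(seq_along(genes), breaks = params$n_bins, labels = FALSE))
  names(bin) <- genes

  set.seed(params$seed)
  pool <- character(0)
  for (g in sort(program)) {
    cand <- sort(setdiff(genes[bin == bin[g]], program))
    if (!length(cand)) cand <- g   # degenerate bin: gene is its own control
    draw <- if (length(cand) >= params$n_ctrl) {
      sample(cand, params$n_ctrl)
    } else {
      sample(cand, params$n_ctrl, replace = TRUE)
    }
    pool <- c(pool, draw)
  }
  prog_mean <- Matrix::rowMeans(norm[, program, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(norm[, pool, drop = FALSE])
  stats::setNames(as.numeric(prog_mean - ctrl_mean), rownames(norm))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact when the samples are tie-free and `n * m <= 10000` (closed-form
#' exact distribution). For tied samples small enough to enumerate
#' (`choose(n + m, n) <= 20000`) the exact two-sided p-value is computed by
#' full enumeration over midranks. Otherwise a tie-corrected normal
#' approximation with continuity correction is used. The method used is
#' recorded in the result.
#'
#' @param a,b Numeric samples (nonempty).
#' @return List with `p_value`, `statistic` (Mann-Whitney U of `a`) and
#'   `method` (`"exact"`, `"exact_enumeration"` or `"normal_approx"`).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) .stopf("both samples must be nonempty")
  n <- length(a); m <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && n * m <= 10000) {
    wt <- stats::wilcox.test(a, b, exact = TRUE)
    return(list(p_value = wt$p.value, statistic = unname(wt$statistic),
                method = "exact"))
  }
  if (choose(n + m, n) <= 20000) {
    r <- rank(c(a, b))
    obs <- sum(r[seq_len(n)])
    combos <- utils::combn(n + m, n)
    sums <- colSums(matrix(r[combos], nrow = n))
    mu <- n * (sum(r)) / (n + m)
    p <- mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
    return(list(p_value = p, statistic = obs - n * (n + 1) / 2,
                method = "exact_enumeration"))
  }
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       method = "normal_approx")
}

#' Holm step-down adjustment
#'
#' @param pvals Numeric vector of p-values in \eqn{[0, 1]}.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Hodges-Lehmann location shift
#'
#' The median of all `n * m` pairwise differences `b_j - a_i`; with `a` the
#' control sample and `b` the treatment (knockout) sample this is the
#' location-shift effect size reported alongside the Wilcoxon test.
#'
#' @param a Control sample.
#' @param b Treatment sample.
#' @return The median pairwise difference (b minus a).
#' @export
hodges_lehmann_shift <- function(a, b) {
  if (!length(a) || !length(b)) .stopf("both samples must be nonempty")
  stats::median(as.numeric(outer(b, a, "-")))
}

#' Compare module scores between two groups
#'
#' Per program: two-sided Wilcoxon p-value, Holm adjustment across programs,
#' and the Hodges-Lehmann location shift (treatment minus reference) as
#' effect size. The table is sorted by adjusted p-value.
#'
#' @param scores Cells x programs matrix (or data.frame) of module scores.
#' @param group Per-cell group labels (exactly two levels).
#' @param ref Reference (control) group label; the other level is the
#'   treatment. Defaults to the first sorted level.
#' @return `data.frame` with `program`, `p_raw`, `p_holm`, `effect`,
#'   `method`, `n_ref`, `n_alt`, sorted by `p_holm` then `p_raw`.
#' @export
compare_module_scores <- function(scores, group, ref = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(group)) .stopf("scores and group must be aligned")
  levs <- sort(unique(as.character(group)))
  if (length(levs) != 2) .stopf("need exactly 2 groups, got %d", length(levs))
  ref <- ref %||% levs[1]
  if (!ref %in% levs) .stopf("ref group '%s' not present", ref)
  alt <- setdiff(levs, ref)
  ia <- group == ref; ib <- group == alt
  if (sum(ia) < 2 || sum(ib) < 2) .stopf("each group needs >= 2 cells")
  res <- lapply(colnames(scores), function(pr) {
    a <- scores[ia, pr]; b <- scores[ib, pr]
    wt <- wilcoxon_rank_sum(a, b)
    data.frame(program = pr, p_raw = wt$p_value,
               effect = hodges_lehmann_shift(a, b), method = wt$method,
               n_ref = sum(ia), n_alt = sum(ib), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_holm <- holm_adjust(res$p_raw)
  res <- res[order(res$p_holm, res$p_raw, res$program),
             c("program", "p_raw", "p_holm", "effect", "method", "n_ref", "n_alt")]
  rownames(res) <- NULL
  res
}

#' Cell-type composition per condition
#'
#' Counts and proportions of final labels per condition. Doublets,
#' unclassified cells and non-quantifiable mixed labels (those containing a
#' non-endocrine constituent) are excluded; proportions sum to 1 within each
#' condition.
#'
#' @param final Output of [finalize_labels()].
#' @param condition Per-cell condition labels aligned with `final`.
#' @return `data.frame` with `condition`, `label`, `n`, `proportion`.
#' @export
composition_table <- function(final, condition) {
  if (nrow(final) != length(condition)) .stopf("final and condition must be aligned")
  keep <- final$status %in% c("singlet", "polyhormonal") & final$quantifiable
  df <- data.frame(condition = as.character(condition)[keep],
                   label = final$final_label[keep], stringsAsFactors = FALSE)
  tab <- as.data.frame(table(df$condition, df$label), stringsAsFactors = FALSE)
  names(tab) <- c("condition", "label", "n")
  tot <- stats::ave(tab$n, tab$condition, FUN = sum)
  tab$proportion <- ifelse(tot > 0, tab$n / tot, 0)
  tab <- tab[order(tab$condition, -tab$n, tab$label), ]
  rownames(tab) <- NULL
  tab
}

#' Alpha- and beta-cell mass and their ratio
#'
#' `mass = (cell area / total tissue area) * pancreatic weight`, computed for
#' the alpha and beta stains of the same pancreas; the ratio is alpha mass
#' over beta mass.
#'
#' @param alpha,beta Lists with `cell_area`, `total_tissue_area` (same
#'   units) and `pancreatic_weight` (mg).
#' @return List with `alpha_mass`, `beta_mass` (mg) and `ratio`.
#' @export
ab_mass_ratio <- function(alpha, beta) {
  check <- function(x, nm) {
    need <- c("cell_area", "total_tissue_area", "pancreatic_weight")
    miss <- setdiff(need, names(x))
    if (length(miss)) .stopf("%s inputs missing: %s", nm, paste(miss, collapse = ", "))
    if (x$cell_area < 0 || x$cell_area > x$total_tissue_area)
      .stopf("%s cell_area must lie in [0, total_tissue_area]", nm)
    if (x$pancreatic_weight <= 0) .stopf("%s pancreatic_weight must be > 0", nm)
  }
  check(alpha, "alpha"); check(beta, "beta")
  am <- alpha$cell_area / alpha$total_tissue_area * alpha$pancreatic_weight
  bm <- beta$cell_area / beta$total_tissue_area * beta$pancreatic_weight
  if (bm == 0) .stopf("beta-cell mass is zero; ratio undefined")
  list(alpha_mass = am, beta_mass = bm, ratio = am / bm)
}

#' Differential-expression parameters
#'
#' Published gates: genes expressed in at least `min_pct` of cells in either
#' condition are tested; a gene is significant when `|log2FC| >
#' lfc_threshold` and the Benjamini-Hochberg adjusted p-value is below
#' `alpha`.
#'
#' @param min_pct Minimum detection fraction (default 0.01).
#' @param lfc_threshold Absolute log2 fold-change gate (default 0.5).
#' @param alpha Adjusted-p gate (default 0.05).
#' @return A list of class `de_params`.
#' @export
de_params <- function(min_pct = 0.01, lfc_threshold = 0.5, alpha = 0.05) {
  if (min_pct < 0 || min_pct > 1) .stopf("min_pct must lie in [0, 1]")
  structure(list(min_pct = min_pct, lfc_threshold = lfc_threshold, alpha = alpha),
            class = "de_params")
}

#' Per-gene differential expression between conditions
#'
#' Rank-based single-cell DE screen between two conditions within one cell
#' population: genes detected in at least `min_pct` of cells in either
#' condition are tested with a two-sided Wilcoxon rank-sum test
#' (tie-corrected normal approximation), p-values are Benjamini-Hochberg
#' adjusted, and log2 fold changes use pseudocount 1 on mean normalized
#' expression (treatment over reference).
#'
#' @param norm Cells x genes normalized matrix (cells of one type).
#' @param condition Per-cell condition labels (two levels).
#' @param params A [de_params()].
#' @param ref Reference condition (default first sorted level).
#' @return `data.frame` with `gene`, `log2_fc`, `pct_ref`, `pct_alt`,
#'   `p_value`, `p_adj`, `significant`, sorted by `p_adj`.
#' @export
de_between_conditions <- function(norm, condition, params = de_params(),
                                  ref = NULL) {
  if (nrow(norm) != length(condition)) .stopf("norm and condition must be aligned")
  levs <- sort(unique(as.character(condition)))
  if (length(levs) != 2) .stopf("need exactly 2 conditions, got %d", length(levs))
  ref <- ref %||% levs[1]
  alt <- setdiff(levs, ref)
  ia <- condition == ref; ib <- condition == alt
  if (sum(ia) < 3 || sum(ib) < 3) .stopf("each condition needs >= 3 cells")
  pct_ref <- Matrix::colMeans(norm[ia, , drop = FALSE] > 0)
  pct_alt <- Matrix::colMeans(norm[ib, , drop = FALSE] > 0)
  testable <- pmax(pct_ref, pct_alt) >= params$min_pct
  sub <- as.matrix(norm[, testable, drop = FALSE])
  p <- .rank_sum_matrix(sub, ib)
  lfc <- .log2_fc(sub, ib)
  p_adj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(gene = colnames(sub), log2_fc = as.numeric(lfc),
                    pct_ref = as.numeric(pct_ref[testable]),
                    pct_alt = as.numeric(pct_alt[testable]),
                    p_value = p, p_adj = p_adj,
                    significant = abs(lfc) > params$lfc_threshold & p_adj < params$alpha,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_adj, res$p_value, res$gene), ]
  rownames(res) <- NULL
  res
}

#' Read gene programs from TSV or YAML
#'
#' TSV layout: two columns `program`, `gene`. YAML layout: a mapping of
#' program name to gene list.
#'
#' @param path File path (`.tsv`/`.txt` or `.yaml`/`.yml`).
#' @return Named list of character vectors.
#' @export
read_programs <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    progs <- lapply(raw, as.character)
  } else {
    df <- .read_tsv(path)
    miss <- setdiff(c("program", "gene"), names(df))
    if (length(miss)) .stopf("program TSV missing columns: %s", paste(miss, collapse = ", "))
    progs <- split(as.character(df$gene), df$program)
  }
  bad <- names(progs)[vapply(progs, function(g) !length(g) || anyDuplicated(g) > 0, logical(1))]
  if (length(bad)) .stopf("program(s) empty or with duplicate genes: %s", paste(bad, collapse = ", "))
  progs
}
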