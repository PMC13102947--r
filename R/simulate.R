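#' Build a synthetic islet simulation configuration
#'
#' Returns a complete, validated configuration for [simulate_islets()]
#' describing a two-condition (ctrl / ko) droplet scRNA-seq experiment over
#' the nine islet cell types of [islet_cell_types()]. Counts are negative
#' binomial around per-type expected expression fractions, library sizes are
#' lognormal, a fraction `ambient_fraction` of every cell's non-mitochondrial
#' budget follows the abundance-weighted tissue-average profile, doublets sum
#' two full singlet transcriptomes, and polyhormonal cells are sampled from an
#' in-between mean profile of two endocrine types.
#'
#' Default conditions: `small` is ~3000 cells total (1500 per condition),
#' `paper_like` targets 10000 cells per condition. Defaults plant an 8%
#' doublet rate, a 2% polyhormonal rate at mixing weight 0.5, ambient fraction
#' 0.02, and a KO composition effect halving the beta-cell weight.
#'
#' @param scale `"small"` or `"paper_like"`.
#' @param seed Integer seed; all randomness in [simulate_islets()] flows from it.
#' @param ... Named overrides for any top-level configuration field
#'   (e.g. `doublet_rate = 0`, `ambient_fraction = 0`).
#' @return A validated list of class `islet_sim_config`. Key fields:
#'   `cells_per_type` (map type to count per condition), `mu` (types x genes
#'   expected expression fractions, rows sum to 1), `dispersion` (per-gene NB
#'   size), `libsize_logmean`/`libsize_logsd`, `doublet_rate`,
#'   `polyhormonal_rate`, `polyhormonal_weight`, `ambient_fraction`,
#'   `condition_effects`, `mito_*` (beta-distributed mitochondrial share),
#'   `panel`, `qc_defaults`, `seed`.
#' @export
islet_sim_config <- function(scale = c("small", "paper_like"), seed = 1L, ...) {
  scale <- match.arg(scale)
  types <- islet_cell_types()
  panel <- default_marker_panel()

  n_sig <- 12L
  n_hk <- 72L
  sig_genes <- lapply(types, function(ty) sprintf("%s.sig%02d", ty, seq_len(n_sig)))
  names(sig_genes) <- types
  hk_genes <- sprintf("Hk%03d", seq_len(n_hk))
  mito_genes <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Co3", "mt-Atp6",
                  "mt-Atp8", "mt-Cytb", "mt-Nd3", "mt-Nd4", "mt-Nd4l",
                  "mt-Nd5", "mt-Nd6")
  genes_nonmito <- c(panel$marker, unlist(sig_genes, use.names = FALSE), hk_genes)

  # expected expression fractions per type: own marker and signature genes
  # elevated, housekeeping shared by all types
  hk_w <- exp(seq(log(0.3), log(3), length.out = n_hk))
  mu <- matrix(0, nrow = length(types), ncol = length(genes_nonmito),
               dimnames = list(types, genes_nonmito))
  for (ty in types) {
    w <- stats::setNames(numeric(length(genes_nonmito)), genes_nonmito)
    w[hk_genes] <- hk_w
    for (other in types) w[sig_genes[[other]]] <- if (other == ty) 3 else 0.3
    own_marker <- panel$marker[panel$cell_type == ty]
    w[own_marker] <- 5
    mu[ty, ] <- w / sum(w)
  }

  dispersion <- stats::setNames(rep(1.5, length(genes_nonmito) + length(mito_genes)),
                                c(genes_nonmito, mito_genes))
  dispersion[panel$marker] <- 3
  dispersion[unlist(sig_genes, use.names = FALSE)] <- 2
  dispersion[mito_genes] <- 2

  comp <- c(alpha = 0.20, beta = 0.55, delta = 0.08, pp = 0.05, ductal = 0.04,
            endothelial = 0.03, mesenchymal = 0.02, immune = 0.02, tcell = 0.01)
  comp <- comp[types]
  n_cond <- if (scale == "small") 1500L else 10000L
  cells_per_type <- stats::setNames(.apportion(comp, n_cond), types)

  cfg <- list(
    scale = scale,
    conditions = c("ctrl", "ko"),
    cells_per_type = cells_per_type,
    gene_panel = list(markers = panel$marker, signature = sig_genes,
                      housekeeping = hk_genes, mito = mito_genes),
    mu = mu,
    dispersion = dispersion,
    libsize_logmean = log(5000),
    libsize_logsd = 0.35,
    doublet_rate = 0.08,
    polyhormonal_rate = 0.02,
    polyhormonal_weight = 0.5,
    ambient_fraction = 0.02,
    mito_shape1 = 2,
    mito_shape2 = 38,
    mito_outlier_rate = 0.03,
    mito_outlier_shape2 = 8,
    mito_weights = {
      w <- exp(seq(log(3), log(0.3), length.out = length(mito_genes)))
      stats::setNames(w / sum(w), mito_genes)
    },
    condition_effects = list(
      ctrl = list(composition = NULL, programs = list()),
      ko = list(composition = c(beta = 0.5), programs = list())
    ),
    panel = panel,
    qc_defaults = list(min_features = 50L, max_features = 1000L,
                       max_mito_fraction = 0.1, mito_prefix = "mt-"),
    seed = as.integer(seed)
  )

  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) .stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "islet_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks rates and fractions lie in \eqn{[0,1]}, the polyhormonal mixing
#' weight in \eqn{(0,1)}, per-type expression fractions sum to one, cell
#' counts are positive integers, and that doublet and polyhormonal rates do
#' not jointly exhaust the dataset.
#'
#' @param cfg An `islet_sim_config`.
#' @return `cfg`, invisibly, or an error.
#' @export
validate_sim_config <- function(cfg) {
  rates <- c(doublet_rate = cfg$doublet_rate,
             polyhormonal_rate = cfg$polyhormonal_rate,
             ambient_fraction = cfg$ambient_fraction,
             mito_outlier_rate = cfg$mito_outlier_rate)
  bad <- rates < 0 | rates > 1
  if (any(bad)) .stopf("rates/fractions out of [0,1]: %s", paste(names(rates)[bad], collapse = ", "))
  if (cfg$polyhormonal_weight <= 0 || cfg$polyhormonal_weight >= 1)
    .stopf("polyhormonal_weight must lie strictly in (0,1)")
  if (cfg$doublet_rate + cfg$polyhormonal_rate >= 1)
    .stopf("doublet_rate + polyhormonal_rate must be < 1")
  if (any(cfg$cells_per_type <= 0) || any(cfg$cells_per_type != round(cfg$cells_per_type)))
    .stopf("cells_per_type must be positive integers")
  if (sum(cfg$cells_per_type) == 0) .stopf("configuration yields zero cells")
  rs <- rowSums(cfg$mu)
  if (any(abs(rs - 1) > 1e-8)) .stopf("mu rows must each sum to 1")
  if (any(cfg$mu < 0)) .stopf("mu must be nonnegative")
  if (!all(colnames(cfg$mu) %in% names(cfg$dispersion)))
    .stopf("dispersion missing for some genes")
  invisible(cfg)
}

# per-condition type weights after composition effects, renormalized so the
# condition keeps its configured total cell number
.condition_weights <- function(cfg, cond) {
  w <- cfg$cells_per_type / sum(cfg$cells_per_type)
  mult <- cfg$condition_effects[[cond]]$composition
  if (!is.null(mult)) {
    unknown <- setdiff(names(mult), names(w))
    if (length(unknown)) .stopf("composition multiplier for unknown type: %s",
                                paste(unknown, collapse = ", "))
    w[names(mult)] <- w[names(mult)] * mult
  }
  w / sum(w)
}

# condition-specific expression profiles after per-program scale effects
.condition_mu <- function(cfg, cond) {
  mu <- cfg$mu
  for (pr in cfg$condition_effects[[cond]]$programs) {
    genes <- intersect(pr$genes, colnames(mu))
    tys <- pr$cell_type %||% rownames(mu)
    for (ty in tys) {
      mu[ty, genes] <- mu[ty, genes] * pr$scale
      mu[ty, ] <- mu[ty, ] / sum(mu[ty, ])
    }
  }
  mu
}

#' Simulate a two-condition islet scRNA-seq dataset with ground truth
#'
#' Generates UMI counts for every configured cell. Singlet counts are negative
#' binomial with mean `lib * ((1 - lambda) * mu[type, ] + lambda * ambient)`,
#' where `ambient` is the type-abundance-weighted average profile of the
#' condition. Doublets are the elementwise sum of two independently simulated
#' singlets of two distinct types. Polyhormonal cells are singlets drawn from
#' the mixed mean profile `w * mu[a] + (1 - w) * mu[b]` of two endocrine
#' types. Mitochondrial genes receive additional counts targeting a per-cell
#' Beta-distributed share of the final total, with a configurable outlier
#' fraction drawn from a heavier-tailed Beta to create QC failures.
#'
#' All randomness flows from `cfg$seed` in a fixed draw order, so the same
#' configuration reproduces bit-identical output.
#'
#' @param cfg An [islet_sim_config()].
#' @return A list of class `islet_sim` with elements `counts` (sparse
#'   cells x genes integer UMI matrix), `truth` (per-cell `data.frame`:
#'   `barcode`, `condition`, `true_type`, `is_doublet`,
#'   `doublet_constituents`, `is_polyhormonal`, `polyhormonal_weight`,
#'   `library_size`) and `config`.
#' @export
simulate_islets <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  types <- names(cfg$cells_per_type)
  if (!all(types %in% rownames(cfg$mu)))
    .stopf("cells_per_type names missing from mu: %s",
           paste(setdiff(types, rownames(cfg$mu)), collapse = ", "))
  genes_nm <- colnames(cfg$mu)
  mito <- names(cfg$mito_weights)
  genes <- c(genes_nm, mito)
  endo <- .endocrine_types(cfg$panel)
  endo <- intersect(types, endo)

  out_counts <- vector("list", length(cfg$conditions))
  out_truth <- vector("list", length(cfg$conditions))

  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[ci]
    w <- .condition_weights(cfg, cond)
    mu <- .condition_mu(cfg, cond)[types, , drop = FALSE]
    ambient <- as.numeric(w %*% mu)
    N <- sum(cfg$cells_per_type)
    n_doub <- round(cfg$doublet_rate * N)
    n_poly <- round(cfg$polyhormonal_rate * N)
    n_sing <- N - n_doub - n_poly
    if (n_sing < 0) .stopf("doublet/polyhormonal rates leave no singlets")

    sing_types <- rep(types, .apportion(w, n_sing))

    # doublet constituents: two distinct types by abundance
    doub_pairs <- matrix(character(0), nrow = 0, ncol = 2)
    if (n_doub > 0) {
      t1 <- sample(types, n_doub, replace = TRUE, prob = w)
      t2 <- vapply(t1, function(a) {
        p <- w[setdiff(types, a)]
        sample(names(p), 1L, prob = p)
      }, character(1))
      doub_pairs <- cbind(t1, unname(t2))
    }

    # polyhormonal constituents: distinct endocrine pairs, weight ~ product
    poly_pairs <- matrix(character(0), nrow = 0, ncol = 2)
    if (n_poly > 0) {
      if (length(endo) < 2) .stopf("polyhormonal cells require >= 2 endocrine types")
      prs <- utils::combn(sort(endo), 2)
      pw <- w[prs[1, ]] * w[prs[2, ]]
      idx <- sample(ncol(prs), n_poly, replace = TRUE, prob = pw)
      poly_pairs <- t(prs[, idx, drop = FALSE])
    }

    # component table: doublets contribute two components
    comp_type <- c(sing_types, as.vector(t(doub_pairs)))
    n_comp <- n_sing + 2L * n_doub + n_poly
    P <- matrix(0, nrow = n_comp, ncol = length(genes_nm))
    if (length(comp_type)) P[seq_along(comp_type), ] <- mu[comp_type, , drop = FALSE]
    if (n_poly > 0) {
      wp <- cfg$polyhormonal_weight
      P[n_sing + 2L * n_doub + seq_len(n_poly), ] <-
        wp * mu[poly_pairs[, 1], , drop = FALSE] +
        (1 - wp) * mu[poly_pairs[, 2], , drop = FALSE]
    }

    lib <- stats::rlnorm(n_comp, cfg$libsize_logmean, cfg$libsize_logsd)
    outlier <- stats::runif(n_comp) < cfg$mito_outlier_rate
    m_share <- ifelse(outlier,
                      stats::rbeta(n_comp, cfg$mito_shape1, cfg$mito_outlier_shape2),
                      stats::rbeta(n_comp, cfg$mito_shape1, cfg$mito_shape2))

    lam <- cfg$ambient_fraction
    mean_nm <- lib * ((1 - lam) * P + lam * matrix(ambient, n_comp, length(genes_nm), byrow = TRUE))
    # mito counts are additional, targeting share m of the final total
    mean_mt <- (lib * m_share / (1 - m_share)) %o% cfg$mito_weights
    mean_all <- cbind(mean_nm, mean_mt)
    size <- cfg$dispersion[genes]
    counts <- matrix(
      stats::rnbinom(n_comp * length(genes),
                     mu = as.numeric(mean_all),
                     size = rep(size, each = n_comp)),
      nrow = n_comp, ncol = length(genes)
    )

    # collapse doublet components into droplets
    cell_of_comp <- c(seq_len(n_sing),
                      n_sing + rep(seq_len(n_doub), each = 2L),
                      n_sing + n_doub + seq_len(n_poly))
    cell_counts <- rowsum(counts, group = cell_of_comp, reorder = TRUE)
    cell_lib <- as.numeric(rowsum(matrix(lib, ncol = 1), group = cell_of_comp, reorder = TRUE))

    sort_pair <- function(m) apply(m, 1, function(x) paste(sort(x), collapse = "+"))
    truth <- data.frame(
      condition = cond,
      true_type = c(sing_types,
                    if (n_doub) sort_pair(doub_pairs) else character(0),
                    if (n_poly) sort_pair(poly_pairs) else character(0)),
      is_doublet = rep(c(FALSE, TRUE, FALSE), c(n_sing, n_doub, n_poly)),
      doublet_constituents = c(rep("", n_sing),
                               if (n_doub) sort_pair(doub_pairs) else character(0),
                               rep("", n_poly)),
      is_polyhormonal = rep(c(FALSE, FALSE, TRUE), c(n_sing, n_doub, n_poly)),
      polyhormonal_weight = c(rep(NA_real_, n_sing + n_doub),
                              rep(cfg$polyhormonal_weight, n_poly)),
      library_size = cell_lib,
      stringsAsFactors = FALSE
    )

    perm <- sample.int(N)
    cell_counts <- cell_counts[perm, , drop = FALSE]
    truth <- truth[perm, , drop = FALSE]
    truth$barcode <- sprintf("%s-%05d", cond, seq_len(N))
    rownames(truth) <- NULL
    out_counts[[ci]] <- cell_counts
    out_truth[[ci]] <- truth
  }

  truth <- do.call(rbind, out_truth)
  truth <- truth[, c("barcode", "condition", "true_type", "is_doublet",
                     "doublet_constituents", "is_polyhormonal",
                     "polyhormonal_weight", "library_size")]
  counts <- .as_count_matrix(do.call(rbind, out_counts), truth$barcode, genes)
  structure(list(counts = counts, truth = truth, config = cfg),
            class = "islet_sim")
}

#' @export
print.islet_sim <- function(x, ...) {
  cat(sprintf("islet_sim: %d cells x %d genes (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$truth$condition)),
                            as.integer(table(x$truth$condition))), collapse = ", ")))
  cat(sprintf("  doublets: %d, polyhormonal: %d\n",
              sum(x$truth$is_doublet), sum(x$truth$is_polyhormonal)))
  invisible(x)
}

#' Write a simulated dataset as 10x-style bundles
#'
#' Writes one 10x triplet (`matrix.mtx`, `features.tsv`, `barcodes.tsv`,
#' optionally gzipped) per condition under `dir/<condition>/`, plus the ground
#' truth as `ground_truth.tsv` keyed by barcode.
#'
#' @param sim An `islet_sim`.
#' @param dir Output directory (created if needed).
#' @param gzip Write gzipped triplet members.
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir, gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in unique(sim$truth$condition)) {
    keep <- sim$truth$condition == cond
    write_10x(sim$counts[sim$truth$barcode[keep], , drop = FALSE],
              file.path(dir, cond), gzip = gzip)
  }
  .write_tsv(sim$truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
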