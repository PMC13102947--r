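# small helper: a normalized matrix with named marker columns
marker_matrix <- function(rows) {
  panel <- default_marker_panel()
  m <- matrix(0, length(rows), nrow(panel),
              dimnames = list(sprintf("c%02d", seq_along(rows)), panel$marker))
  for (i in seq_along(rows)) m[i, names(rows[[i]])] <- unlist(rows[[i]])
  m
}

test_that("marker gating implements the strict one-marker rule", {
  m <- marker_matrix(list(
    c(Gcg = 3.0),                 # pure alpha (Gcg > 2.1)
    c(Gcg = 3.0, Ins1 = 2.5),     # mixed candidate
    c(Gcg = 2.1),                 # at threshold: not above (strict >)
    c()                           # unassigned
  ))
  g <- gate_cells(m, default_marker_panel())
  expect_equal(g$status, c("pure", "candidate_mixed", "unassigned", "unassigned"))
  expect_equal(g$gate_type[1], "alpha")
  expect_equal(g$markers_above[2], "Gcg,Ins1")
  expect_error(gate_cells(m[, -1], default_marker_panel()), "Gcg")
})

test_that("top discriminative genes form the expected feature union", {
  panel <- default_marker_panel()
  types <- panel$cell_type
  sig <- lapply(types, function(ty) sprintf("%s.g%02d", ty, 1:9))
  names(sig) <- types
  genes <- c(panel$marker, unlist(sig), sprintf("Hk%02d", 1:10))
  cells_per_type <- 5
  norm <- matrix(0, cells_per_type * length(types), length(genes),
                 dimnames = list(sprintf("c%03d", 1:(cells_per_type * length(types))), genes))
  truth <- rep(types, each = cells_per_type)
  for (i in seq_len(nrow(norm))) {
    ty <- truth[i]
    norm[i, panel$marker[panel$cell_type == ty]] <- 3
    norm[i, sig[[ty]]] <- 2
    norm[i, sprintf("Hk%02d", 1:10)] <- 1
  }
  gate <- gate_cells(norm, panel)
  expect_true(all(gate$status == "pure"))
  res <- top_discriminative_genes(norm, gate, panel, k = 10)
  # each type's top 10 = its marker + its 9 unique genes; union with the
  # panel gives 9 + 81 = 90 features with no duplicates
  expect_length(res$features, 90)
  expect_false(any(duplicated(res$features)))
  expect_setequal(res$per_type$beta, c("Ins1", sig$beta))
  expect_identical(res$features[1:9], panel$marker)

  res0 <- top_discriminative_genes(norm, gate, panel, k = 0)
  expect_identical(res0$features, panel$marker)

  gate_bad <- gate
  gate_bad$status[truth == "delta"] <- "unassigned"
  expect_error(top_discriminative_genes(norm, gate_bad, panel), "delta")
})

test_that("pure centroids are means of pure-profile cells", {
  gate <- data.frame(barcode = c("a", "b", "c", "d"),
                     markers_above = "", n_markers = 1L,
                     status = c("pure", "pure", "pure", "candidate_mixed"),
                     gate_type = c("alpha", "alpha", "beta", NA),
                     stringsAsFactors = FALSE)
  sc <- matrix(c(1, 0, 3, 0, 0, 1, 9, 9), 4, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c", "d"), c("g1", "g2")))
  cs <- build_centroids(sc, gate, c("g1", "g2"))
  expect_equal(cs$centroids["alpha", ], c(g1 = 2, g2 = 0))   # mean of (1,0),(3,0)
  expect_equal(cs$centroids["beta", ], c(g1 = 0, g2 = 1))
  # permuting cells leaves centroids unchanged
  perm <- c(3, 1, 4, 2)
  cs2 <- build_centroids(sc[perm, ], gate[perm, ], c("g1", "g2"))
  expect_equal(cs2$centroids, cs$centroids)
})

test_that("mixed centroids are unweighted means with full combinatorics", {
  feats <- c("g1", "g2")
  pure <- structure(list(
    features = feats,
    centroids = matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE,
                       dimnames = list(c("a", "b", "c"), feats)),
    order = c(a = 1L, b = 1L, c = 1L)), class = "centroid_set")
  cs <- build_mixed_centroids(pure)
  expect_equal(unname(cs$centroids["a+b", ]), c(0.5, 0.5))
  expect_equal(nrow(cs$centroids), 3 + 3 + 1)
  # identical pure centroids average to themselves
  same <- pure
  same$centroids[] <- rep(c(2, 5), each = 3)
  cs_same <- build_mixed_centroids(same)
  expect_equal(unname(cs_same$centroids["a+b+c", ]), c(2, 5))
  # n-type generalization: n + C(n,2) + C(n,3)
  for (n in 3:12) {
    labels <- sprintf("t%02d", seq_len(n))
    p <- structure(list(
      features = feats,
      centroids = matrix(rnorm(n * 2), n, 2, dimnames = list(labels, feats)),
      order = stats::setNames(rep(1L, n), labels)), class = "centroid_set")
    cs_n <- build_mixed_centroids(p)
    expect_equal(nrow(cs_n$centroids), n + choose(n, 2) + choose(n, 3))
  }
})

test_that("maximum-correlation classification handles exact and mixed profiles", {
  feats <- sprintf("g%d", 1:4)
  cent <- rbind(alpha = c(1, -1, 0, 0), beta = c(0, 0, 1, -1),
                delta = c(-1, 0, 0, 1))
  colnames(cent) <- feats
  cs <- build_mixed_centroids(structure(list(
    features = feats, centroids = cent,
    order = c(alpha = 1L, beta = 1L, delta = 1L)), class = "centroid_set"),
    orders = 2L)
  cells <- rbind(x1 = cent["alpha", ],                      # exact pure profile
                 x2 = (cent["alpha", ] + cent["beta", ]) / 2,  # exact mixture
                 x3 = c(5, 5, 5, 5))                        # constant: no cor
  res <- classify_by_correlation(cells, cs)
  expect_equal(res$best_label[1], "alpha")
  expect_equal(res$best_correlation[1], 1, tolerance = 1e-12)
  expect_equal(res$best_label[2], "alpha+beta")
  expect_equal(res$label_order[2], 2L)
  expect_equal(res$status[3], "unclassified")
  expect_true(is.na(res$best_label[3]))
})

test_that("classification is invariant to affine transforms of a cell", {
  set.seed(8)
  feats <- sprintf("g%d", 1:12)
  cent <- matrix(rnorm(5 * 12), 5, 12,
                 dimnames = list(sprintf("t%d", 1:5), feats))
  cs <- build_mixed_centroids(structure(list(
    features = feats, centroids = cent,
    order = stats::setNames(rep(1L, 5), rownames(cent))), class = "centroid_set"))
  cells <- matrix(rnorm(10 * 12), 10, 12,
                  dimnames = list(sprintf("c%d", 1:10), feats))
  base <- classify_by_correlation(cells, cs)
  trans <- classify_by_correlation(cells * 3.7 + 2.2, cs)
  expect_identical(base$best_label, trans$best_label)
})

test_that("classifier agrees with the brute-force oracle cell-for-cell", {
  set.seed(21)
  sim <- simulate_islets(tiny_config(n_per_condition = 300L, seed = 21L))
  norm <- normalize_log(sim$counts)
  scaled <- scale_genes(norm)
  g <- gate_cells(norm)
  feats <- top_discriminative_genes(norm, g)
  cs <- build_mixed_centroids(build_centroids(scaled, g, feats$features))
  cells <- scaled[sample(nrow(scaled), 50), , drop = FALSE]
  fast <- classify_by_correlation(cells, cs)
  slow <- brute_force_classify(cells, cs)
  expect_identical(fast$best_label, slow)
})

test_that("zero-variance centroids are excluded with a warning", {
  feats <- c("g1", "g2", "g3")
  cent <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), flat = c(2, 2, 2))
  colnames(cent) <- feats
  cs <- structure(list(features = feats, centroids = cent,
                       order = c(a = 1L, b = 1L, flat = 1L)),
                  class = "centroid_set")
  cells <- matrix(c(1, 0.1, 0), 1, 3, dimnames = list("c1", feats))
  expect_warning(res <- classify_by_correlation(cells, cs), "flat")
  expect_equal(res$best_label, "a")
})

test_that("centroid sets round-trip through TSV", {
  dir <- withr::local_tempdir()
  set.seed(3)
  feats <- sprintf("g%d", 1:6)
  cent <- matrix(rnorm(18), 3, 6, dimnames = list(c("a", "b", "c"), feats))
  cs <- build_mixed_centroids(structure(list(
    features = feats, centroids = cent,
    order = c(a = 1L, b = 1L, c = 1L)), class = "centroid_set"))
  path <- file.path(dir, "centroids.tsv")
  write_centroids(cs, path)
  back <- read_centroids(path)
  expect_equal(back$centroids, cs$centroids, tolerance = 1e-10)
  expect_equal(back$order, cs$order)
})
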