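test_that("module score of the whole gene universe is exactly zero", {
  set.seed(4)
  m <- matrix(rpois(50 * 40, 5), 50, 40,
              dimnames = list(sprintf("c%02d", 1:50), sprintf("g%02d", 1:40)))
  norm <- normalize_log(m)
  s <- module_score(norm, colnames(norm), score_params(n_bins = 5, n_ctrl = 3, seed = 1))
  expect_equal(unname(s), rep(0, 50), tolerance = 1e-12)
})

test_that("module score matches the hand computation on a worked fixture", {
  # 4 genes, 2 cells; bins of 2 by average expression; n_ctrl = 1 so the
  # single non-program gene in the program gene's bin is the control
  norm <- rbind(c1 = c(A = 1, B = 2, C = 5, D = 6),
                c2 = c(A = 3, B = 2, C = 5, D = 8))
  # averages: A=2, B=2, C=5, D=7 -> bins {A,B}, {C,D}
  s <- module_score(norm, "A", score_params(n_bins = 2, n_ctrl = 1, seed = 1))
  expect_equal(s, c(c1 = 1 - 2, c2 = 3 - 2))      # score = A - B per cell
  s2 <- module_score(norm, c("A", "D"), score_params(n_bins = 2, n_ctrl = 1, seed = 1))
  # controls: B for A, C for D; score = mean(A,D) - mean(B,C)
  expect_equal(s2, c(c1 = mean(c(1, 6)) - mean(c(2, 5)),
                     c2 = mean(c(3, 8)) - mean(c(2, 5))))
})

test_that("module scores are invariant to gene-order permutation", {
  set.seed(6)
  m <- matrix(rpois(30 * 60, 4), 30, 60,
              dimnames = list(sprintf("c%02d", 1:30), sprintf("g%02d", 1:60)))
  norm <- as.matrix(normalize_log(m))
  prog <- c("g05", "g17", "g33", "g48")
  p <- score_params(n_bins = 6, n_ctrl = 5, seed = 9)
  s1 <- module_score(norm, prog, p)
  s2 <- module_score(norm[, sample(ncol(norm))], prog, p)
  expect_equal(s1, s2)
})

test_that("module score validates its inputs", {
  m <- matrix(1, 3, 10, dimnames = list(letters[1:3], sprintf("g%d", 1:10)))
  expect_error(module_score(m, "g1", score_params(n_bins = 25)), "n_bins")
  expect_warning(s <- module_score(m, c("g1", "nope"), score_params(n_bins = 2, seed = 1)),
                 "dropping")
  expect_error(suppressWarnings(module_score(m, "nope", score_params(n_bins = 2))),
               "empty")
})

test_that("wilcoxon p-values match their closed forms and enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)                    # 2 of C(6,3)=20 assignments
  expect_equal(r$method, "exact")
  r2 <- wilcoxon_rank_sum(0, 1)
  expect_equal(r2$p_value, 1)                     # 2 of 2 arrangements
  r3 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)) # identical: tied, enumerated
  expect_equal(r3$p_value, 1)
  expect_equal(r3$method, "exact_enumeration")
})

test_that("exact wilcoxon agrees with full enumeration for tie-free samples", {
  set.seed(12)
  for (n in c(2, 4, 6, 8)) {
    for (m in c(2, 5, 8)) {
      v <- sample(seq_len(200), n + m)            # distinct: tie-free
      a <- v[seq_len(n)]; b <- v[-seq_len(n)]
      got <- wilcoxon_rank_sum(a, b)
      expect_equal(got$method, "exact")
      expect_equal(got$p_value, wilcoxon_enum_oracle(a, b), tolerance = 1e-12)
    }
  }
})

test_that("tied-sample enumeration agrees with the oracle", {
  set.seed(13)
  for (i in 1:10) {
    a <- sample(1:4, 5, replace = TRUE)
    b <- sample(1:4, 4, replace = TRUE)
    got <- wilcoxon_rank_sum(a, b)
    expect_equal(got$method, "exact_enumeration")
    expect_equal(got$p_value, wilcoxon_enum_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("the matrix rank-sum screen matches wilcox.test's approximation", {
  set.seed(14)
  X <- matrix(c(rpois(200, 3), rpois(200, 4)), nrow = 20, byrow = FALSE)
  grp <- rep(c(TRUE, FALSE), each = 10)
  p <- isletid:::.rank_sum_matrix(X, grp)
  ref <- apply(X, 2, function(x)
    stats::wilcox.test(x[grp], x[!grp], exact = FALSE, correct = TRUE)$p.value)
  expect_equal(p, unname(ref), tolerance = 1e-12)
})

test_that("holm adjustment matches the closed forms and the step-down oracle", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.03, 0.01, 0.04)), c(0.06, 0.03, 0.06))
  set.seed(15)
  grid <- seq(0.01, 1, by = 0.01)
  for (len in 1:5) {
    for (i in 1:40) {
      p <- sample(grid, len, replace = TRUE)
      adj <- holm_adjust(p)
      expect_equal(adj, holm_oracle(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-12))          # never below the input
    }
  }
})

test_that("hodges-lehmann shift equals the brute-force pairwise median", {
  expect_equal(hodges_lehmann_shift(c(1, 2), 3), 1.5)
  expect_equal(hodges_lehmann_shift(5, 5), 0)
  expect_equal(hodges_lehmann_shift(c(0, 0, 0), c(1, 2, 3)), 2)
  set.seed(16)
  for (i in 1:100) {
    n <- sample(1:30, 1); m <- sample(1:30, 1)
    a <- rnorm(n); b <- rnorm(m, mean = 0.5)
    diffs <- numeric(0)
    for (x in a) for (y in b) diffs <- c(diffs, y - x)
    expect_equal(hodges_lehmann_shift(a, b), median(diffs), tolerance = 1e-12)
  }
})

test_that("group comparison of module scores behaves at its edges", {
  scores <- cbind(p1 = c(1, 2, 3, 1, 2, 3), p2 = c(4, 5, 6, 4, 5, 6))
  grp <- rep(c("ctrl", "ko"), each = 3)
  res <- compare_module_scores(scores, grp, ref = "ctrl")
  expect_equal(res$effect, c(0, 0))               # identical groups
  expect_equal(res$p_holm, c(1, 1))
  one <- compare_module_scores(scores[, 1, drop = FALSE], grp)
  expect_equal(one$p_holm, one$p_raw)             # m = 1 identity
})

test_that("a planted shift is detected with the right sign and size", {
  set.seed(17)
  n <- 120
  scores <- cbind(p1 = rnorm(2 * n, sd = 0.3), p2 = rnorm(2 * n, sd = 0.3),
                  p3 = rnorm(2 * n, sd = 0.3))
  grp <- rep(c("ctrl", "ko"), each = n)
  scores[grp == "ko", "p2"] <- scores[grp == "ko", "p2"] + 1
  res <- compare_module_scores(scores, grp, ref = "ctrl")
  expect_equal(res$program[1], "p2")              # smallest adjusted p
  expect_equal(res$effect[res$program == "p2"], 1, tolerance = 0.1)
  expect_lt(res$p_holm[res$program == "p2"], 0.001)
})

test_that("composition proportions sum to one and ignore excluded cells", {
  fin <- data.frame(
    barcode = sprintf("c%d", 1:110),
    status = c(rep("singlet", 100), rep("doublet", 10)),
    final_label = c(rep(c("alpha", "beta"), each = 50), rep("beta", 10)),
    quantifiable = c(rep(TRUE, 100), rep(FALSE, 10)),
    removal_reason = "", stringsAsFactors = FALSE)
  comp <- composition_table(fin, rep("ctrl", 110))
  expect_equal(comp$proportion[comp$label == "alpha"], 0.5)
  expect_equal(comp$proportion[comp$label == "beta"], 0.5)
  expect_equal(sum(comp$proportion), 1)
})

test_that("mass formula and ratio follow the area-fraction definition", {
  r <- ab_mass_ratio(alpha = list(cell_area = 1, total_tissue_area = 100, pancreatic_weight = 200),
                     beta = list(cell_area = 4, total_tissue_area = 100, pancreatic_weight = 200))
  expect_equal(r$alpha_mass, 2)
  expect_equal(r$beta_mass, 8)
  expect_equal(r$ratio, 0.25)
  # equal areas give ratio 1; doubling weight scales masses, not the ratio
  eq <- ab_mass_ratio(alpha = list(cell_area = 3, total_tissue_area = 50, pancreatic_weight = 120),
                      beta = list(cell_area = 3, total_tissue_area = 50, pancreatic_weight = 120))
  expect_equal(eq$ratio, 1)
  dbl <- ab_mass_ratio(alpha = list(cell_area = 1, total_tissue_area = 100, pancreatic_weight = 400),
                       beta = list(cell_area = 4, total_tissue_area = 100, pancreatic_weight = 400))
  expect_equal(dbl$alpha_mass, 2 * r$alpha_mass)
  expect_equal(dbl$ratio, r$ratio)
  expect_error(ab_mass_ratio(alpha = list(cell_area = 1, total_tissue_area = 100, pancreatic_weight = 200),
                             beta = list(cell_area = 0, total_tissue_area = 100, pancreatic_weight = 200)),
               "undefined")
  expect_error(ab_mass_ratio(alpha = list(cell_area = 200, total_tissue_area = 100, pancreatic_weight = 200),
                             beta = list(cell_area = 4, total_tissue_area = 100, pancreatic_weight = 200)),
               "cell_area")
})

test_that("differential expression applies the detection, fold-change and p gates", {
  set.seed(18)
  n <- 30
  genes <- c("up", "flat", "silent", "house", sprintf("noise%02d", 1:20))
  m <- matrix(rpois(2 * n * length(genes), 5), 2 * n, length(genes),
              dimnames = list(sprintf("c%03d", 1:(2 * n)), genes))
  cond <- rep(c("ctrl", "ko"), each = n)
  m[cond == "ko", "up"] <- rpois(n, 60)
  m[, "house"] <- rpois(2 * n, 2000)   # dominant baseline keeps depths comparable
  m[, "silent"] <- 0
  norm <- normalize_log(m)
  res <- de_between_conditions(norm, cond, de_params(), ref = "ctrl")
  expect_false("silent" %in% res$gene)            # excluded by min_pct
  up <- res[res$gene == "up", ]
  expect_true(up$significant)
  expect_gt(up$log2_fc, 0.5)
  expect_lt(up$p_adj, 0.05)
  expect_false(res$significant[res$gene == "flat"])
  expect_error(de_between_conditions(norm[28:32, ], cond[28:32]), ">= 3 cells")
})

test_that("programs round-trip through TSV and YAML", {
  dir <- withr::local_tempdir()
  progs <- list(identity = c("Ins1", "Mafa", "Nkx6-1"), stress = c("Ldha", "Hk1"))
  tsv <- file.path(dir, "programs.tsv")
  df <- data.frame(program = rep(names(progs), lengths(progs)),
                   gene = unlist(progs, use.names = FALSE))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(lapply(read_programs(tsv), sort), lapply(progs, sort))
  yml <- file.path(dir, "programs.yaml")
  yaml::write_yaml(progs, yml)
  expect_equal(read_programs(yml), progs)
  bad <- file.path(dir, "bad.tsv")
  utils::write.table(data.frame(program = "a", gene = c("x", "x")), bad,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_programs(bad), "duplicate")
})
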