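---
title: "Classifying islet cell identity: centroids, doublets, and polyhormonal cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying islet cell identity: centroids, doublets, and polyhormonal cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletid)
```

## The problem

Droplet scRNA-seq of pancreatic islets poses a specific annotation problem:
a single cell expressing two hormones (say insulin and glucagon) is either a
genuinely **polyhormonal cell** — a biologically meaningful state in islet
stress and dedifferentiation — or a **doublet**, two cells captured in one
droplet whose summed transcriptome mimics exactly that mixed profile.
Standard one-label annotation tools cannot make this distinction. This
package implements a workflow built for it:

1. **Marker gating.** Each cell is gated on canonical marker thresholds
   (log-normalized scale, strict `>`): Gcg > 2.1 (alpha), Ins1 > 2.0 (beta),
   Sst > 2 (delta), Ppy > 2.2 (PP), Krt19 > 0.5 (ductal), Cd34 > 0.1
   (endothelial), Vim > 0.6 (mesenchymal), Cd86 > 1 (immune), Trac > 0.1
   (T cell). Cells above exactly one threshold are *pure-profile cells*.
2. **Discriminative features.** Within pure cells, a one-vs-rest Wilcoxon
   screen picks the top 10 genes per type; their union with the marker panel
   is the feature set $F$.
3. **Centroids.** The centroid of a type is the mean z-scaled profile of its
   pure cells over $F$. *Artificial mixed centroids* are added for every
   pair and triple of types as the unweighted mean of the constituent pure
   centroids — with 9 types, $9 + \binom{9}{2} + \binom{9}{3} = 129$
   centroids.
4. **Classification.** Every cell is Pearson-correlated against all 129
   centroids and takes the label of the highest correlation.
5. **Consensus.** A mixed centroid call is one of three mixed-type
   detectors, alongside two simulated-doublet kNN detectors. A **majority
   vote** separates doublets (flagged by more than one approach, removed)
   from *suggestive polyhormonal cells* (mixed centroid call only, retained
   with their mixed label). Mixed labels containing a non-endocrine type are
   kept but dismissed from quantification.
6. **Downstream.** Composition tables per condition; Tirosh-style module
   scores with Wilcoxon/Holm group inference and Hodges–Lehmann effect
   sizes; per-gene rank-based DE with the `log2FC > 0.5`, `p_adj < 0.05`,
   `min.pct = 0.01` gates; and the histology mass formula
   $\text{mass} = \frac{\text{cell area}}{\text{total tissue area}} \times
   \text{pancreatic weight}$.

Every stage is driven by a synthetic islet generator with known ground
truth, so the whole chain is testable at desk scale.

## The synthetic generator: what it emulates

`islet_sim_config()` / `simulate_islets()` produce a two-condition (ctrl /
ko) experiment over nine islet cell types. The statistical structure mirrors
what the classifier assumes about real droplet data:

* **Counts.** Gene $g$ in cell $i$ of type $t$ is negative binomial with
  mean $\ell_i \left[(1-\lambda)\,\mu_{tg} + \lambda\,a_g\right]$, where
  $\mu_t$ is the type's expected expression fraction profile (rows sum to
  1), $\ell_i \sim \text{Lognormal}(\log 5000,\ 0.35)$ is the library size,
  and $a = \sum_t w_t \mu_t$ is the abundance-weighted **ambient** profile
  ($\lambda = 0.02$ by default). NB size is 3 for markers, 2 for signature
  genes, 1.5 for housekeeping.
* **Composition.** Beta 0.55, alpha 0.20, delta 0.08, PP 0.05, ductal 0.04,
  endothelial 0.03, mesenchymal 0.02, immune 0.02, T 0.01 — a realistic
  mouse islet preparation. The ko condition halves the beta weight
  (renormalized within the sample), planting a composition shift for the
  downstream tables to recover.
* **Expression profiles.** Each type has one canonical marker at ~3% of its
  transcriptome (log-normalized values ≈ 5–6, safely above the printed
  thresholds while ambient contamination at $\lambda = 0.02$ stays below
  them) and 12 signature genes elevated 10-fold over their level in other
  types; 72 housekeeping genes are shared. 13 `mt-` genes complete the
  202-gene panel.
* **Doublets** (8%) are the elementwise **sum of two full singlet count
  vectors** of two *distinct* types sampled by abundance — the physical
  two-cells-one-droplet event, including its doubled library size.
  Homotypic doublets are omitted by design: after depth normalization they
  are statistically indistinguishable from singlets and are not the object
  of the doublet-versus-polyhormonal discrimination this workflow targets.
* **Polyhormonal cells** (2%) are singlets drawn from the mixed mean
  profile $w\,\mu_a + (1-w)\,\mu_b$ of two endocrine types ($w = 0.5$ by
  default), i.e. the "in-between profile" assumption made explicit — at a
  *singlet* library size. The true mixing proportion of real polyhormonal
  cells is unknown; $w$ is a free parameter, not a claim about data.
* **Mitochondrial fraction.** Per cell a share $m \sim \text{Beta}(2, 38)$
  (mean 5%), with 3% of cells drawn from the heavier-tailed
  $\text{Beta}(2, 8)$ to create QC failures. Mitochondrial counts are
  generated *on top of* the non-mitochondrial budget with mean
  $\ell_i\, m/(1-m)$, so the realized mitochondrial fraction is ≈ $m$ while
  non-mitochondrial means remain exactly $\ell_i \mu_{tg}$ — keeping the NB
  mean identity testable.
* **One seed.** All draws flow from `cfg$seed` in a fixed order
  (per condition: doublet pairs, polyhormonal pairs, library sizes,
  mitochondrial shares, NB counts, final permutation), so a configuration
  reproduces bit-identical output.

What the generator does **not** emulate: batch effects beyond the condition
label, empty droplets, UMI collisions, gene-length or GC biases, cell-cycle
structure, and continuous differentiation trajectories. Tests passing on
synthetic data therefore demonstrate the *logic* of the workflow — gating,
centroid geometry, vote semantics, statistical calibration — not robustness
to every artifact of real tissue data.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `qc_params()` | 2500 / 6000 / 10% | Strict feature-count and mito gates; the published values assume a genome-wide panel. The simulator's 202-gene panel saturates feature counts, so its `qc_defaults` scale them (50 / 1000), leaving the mito gate as the operative filter. |
| `cluster_params()` | 30 PCs, k = 20, resolution = 2 | SNN-Jaccard graph (prune 1/15) + Louvain modularity. Resolution 2 intentionally over-partitions; labels are auxiliary to the centroid classifier. |
| `k_top` | 10 | Discriminative genes per type; genes enriched *in* the type rank first (positive log2 FC), then p, then effect, then symbol. |
| `expected_doublet_rate` | 0.08 | ~10x loading at 10k cells; the detector flags exactly this score quantile. |
| `score_params()` | 25 bins, 100 controls | Tirosh-style scoring; bin/control counts are the ecosystem's common defaults and are seeded. |
| `de_params()` | min.pct 0.01, \|log2FC\| > 0.5, p_adj < 0.05 | The published DE gates, applied to a rank-based test. |

## Design decisions

* **Normalization.** The reference workflow uses sctransform; this package
  deliberately uses log-CPM (`normalize_log`, `log(1 + 10^4 c/\ell)`) for
  gating and per-gene z-scaling clipped at ±10 (`scale_genes`) for
  centroids. The marker thresholds are defined on the log-normalized
  ("RNA-slot") scale either way; the variance-stabilization difference is a
  documented deviation that does not touch the classifier's logic.
* **Pearson correlation.** The correlation flavor is not dictated by the
  method's description; Pearson is the ecosystem default and is what the
  scaled-profile geometry assumes. Ties break toward the smallest mixture
  order (pure < pair < triple), then lexicographically — deterministic and
  conservative (a tie never invents a mixture).
* **Mixed centroids as unweighted means.** Averaging pure centroids in
  scaled space is the direct formalization of the in-between-profile
  premise; weighted mixtures are exposed via `build_mixed_centroids()`'s
  `weights` argument.
* **Doublet detectors.** The two external tools of the reference workflow
  are replaced by a self-contained simulated-doublet kNN detector run at two
  independent parameter sets (k = 30/10 PCs and k = 15/15 PCs, distinct
  seeds), plus an adapter (`read_detector_flags()`) so real external calls
  can be slotted into the vote. The detector co-embeds observed cells with
  artificial doublets (sums of random observed pairs) and scores each cell
  by the artificial fraction among its k nearest neighbors.
* **The library-size dimension.** By default the detector appends a
  standardized log10 total-UMI axis to the PCA embedding, weighted like the
  leading expression axis. This is the decisive feature for this workflow's
  central discrimination: a genuine doublet carries roughly twice the
  library of a singlet, while a polyhormonal cell shows a mixed *profile*
  at singlet *depth*. Without the depth axis the detectors flag over half
  of true polyhormonal cells (their neighborhoods fill with same-pair
  artificial doublets); with it, polyhormonal cells separate from the
  artificial cloud and the flag rate drops to ~20% while doublet recall
  improves.
* **Vote semantics.** More than one flag ⇒ doublet (removed) — including
  the pattern where both kNN detectors fire but the centroid call is pure,
  which is recorded with the distinct reason `doublet_detectors_only`. A
  lone centroid-mixed call ⇒ suggestive polyhormonal, keeping the mixed
  label. A lone detector flag ⇒ singlet, disagreement noted.
* **Statistics.** Holm adjustment is used across program-level comparisons,
  Benjamini–Hochberg across per-gene DE — two distinct usages, kept
  distinct. The location effect size is the Hodges–Lehmann estimator
  (median of all cross-group pairwise differences, ko − ctrl). Per-gene
  screens use a tie-corrected normal-approximation rank-sum test (matching
  `wilcox.test(exact = FALSE, correct = TRUE)`, asserted in tests);
  `wilcoxon_rank_sum()` itself is exact for tie-free samples with
  $nm \le 10^4$, exact-by-enumeration over midranks for small tied samples
  ($\binom{n+m}{n} \le 2 \times 10^4$), and approximate otherwise, with the
  method recorded. The rank test also stands in for the reference
  workflow's count-model DE on single cells; the adjusted-p and fold-change
  gates are preserved exactly, with log2 fold changes computed on the
  depth-normalized scale with pseudocount 1.

## Numerical choices and degenerate inputs

* Zero-total cells are flagged and left at zero, never divided.
* Zero-variance genes scale to 0; zero-variance *cells* have no defined
  correlation and come back `unclassified`; zero-variance *centroids* are
  excluded with a warning.
* Scaling uses the sample (n − 1) standard deviation, clipped at ±10 to
  bound outlier leverage on centroids.
* `module_score()` bins genes by average expression with ties broken by
  symbol, draws controls from sorted candidate lists, and lets a program
  gene act as its own control when its bin holds no non-program genes — so
  a program spanning the whole universe scores exactly 0, and scores are
  invariant to gene-order permutations of the matrix.
* The detector's flag set is the top `round(rate × n)` scores with ties
  broken by cell index — exact, reproducible counts.
* Identical-cell inputs collapse to a single cluster before graph
  construction; the quantile flag rule still returns deterministic indices.

## Problem sizes

The test suite exercises the full chain on reduced simulations (150–600
cells per condition) and runs the complete default small experiment (3000
cells, 8% doublets, 2% polyhormonal at $w = 0.5$, $\lambda = 0.02$) for the
end-to-end recovery checks; the whole suite completes in well under a
minute. `paper_like` scale (10000 cells per condition) runs in a few
minutes and is intended for interactive use:

```{r, eval = FALSE}
cfg <- islet_sim_config("paper_like", seed = 1)
sim <- simulate_islets(cfg)
res <- run_islet_pipeline(sim$counts, sim$truth$condition,
                          qc = do.call(qc_params, cfg$qc_defaults),
                          out_dir = "islet_run", seed = 1)
```

## Known limitations

* Separation between polyhormonal cells and doublets is imperfect by
  construction — a doublet caught at low depth looks like a polyhormonal
  cell, and a polyhormonal cell in a deep droplet looks like a doublet. The
  recovery rates reported by `scripts/acceptance.R` quantify this on
  synthetic data; they are engineering properties of the workflow, not
  biological claims.
* Polyhormonal cells with genuinely unique (non-intermediate) expression
  cannot be identified by centroid averaging.
* Ambient-profile estimation and removal are out of scope; the generator's
  $\lambda$ exists to stress robustness, not to model a specific removal
  method.
* Cross-sample integration, UMAP layout, enrichment analysis and
  deconvolution are out of scope.
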