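# isletid

Cell-identity classification for pancreatic islet droplet scRNA-seq, with
explicit discrimination between **doublets** (two cells in one droplet) and
**polyhormonal cells** (one cell expressing two or more islet hormones).
Both show a transcriptome intermediate between two cell types; only one of
them is biology. `isletid` is for analysts of islet (or other
mixed-population) single-cell data who need that distinction made
explicitly, reproducibly, and testably.

## The method

Cells passing QC (more than 2500 but fewer than 6000 detected features,
mitochondrial fraction < 10%, all bounds strict) are gated on canonical
marker thresholds on the log-normalized scale (Gcg > 2.1, Ins1 > 2.0,
Sst > 2, Ppy > 2.2, Krt19 > 0.5, Cd34 > 0.1, Vim > 0.6, Cd86 > 1,
Trac > 0.1). Cells exceeding exactly one threshold are *pure-profile cells*
and define, over a discriminative feature set $F$ (top-10 one-vs-rest genes
per type ∪ marker panel), the type **centroids**

$$c_t = \frac{1}{|P_t|} \sum_{i \in P_t} z_i, \qquad
  c_{(s,t)} = \tfrac{1}{2}(c_s + c_t), \qquad
  c_{(s,t,u)} = \tfrac{1}{3}(c_s + c_t + c_u),$$

where $z_i$ is cell $i$'s z-scaled expression over $F$ — with 9 types,
$9 + \binom{9}{2} + \binom{9}{3} = 129$ pure and artificial mixed
centroids. Every cell takes the label
$\arg\max_\ell \; \mathrm{cor}(z_i, c_\ell)$ (Pearson). The mixed-centroid
call then enters a **majority vote** with two simulated-doublet kNN
detectors: more than one flag ⇒ doublet (removed); a lone centroid-mixed
call ⇒ *suggestive polyhormonal cell* (retained, mixed label); mixed labels
containing a non-endocrine type are dismissed from quantification.

Downstream tools: per-condition composition tables, Tirosh-style gene-program
module scores with Wilcoxon/Holm inference and Hodges–Lehmann location
shifts, rank-based per-gene DE with the `|log2FC| > 0.5`, `p_adj < 0.05`,
`min.pct = 0.01` gates, and the histology mass formula
`mass = cell area / total tissue area × pancreatic weight`.

A negative-binomial synthetic islet generator (9 types, lognormal library
sizes, ambient contamination, summed-transcriptome doublets, in-between
polyhormonal profiles, per-condition composition effects, full ground
truth) makes every stage verifiable at desk scale. See the vignette
`vignettes/islet-identity.Rmd` for the model, parameter meanings and design
rationale.

## Worked example

```r
library(isletid)

cfg <- islet_sim_config("small", seed = 1)   # 3000 cells, 2 conditions
sim <- simulate_islets(cfg)
sim
#> islet_sim: 3000 cells x 202 genes (ctrl=1500, ko=1500)
#>   doublets: 240, polyhormonal: 60

res <- run_islet_pipeline(sim$counts, sim$truth$condition,
                          qc = do.call(qc_params, cfg$qc_defaults),
                          seed = 1)
table(res$final$status)
#>      doublet polyhormonal      singlet
#>          230           66         2382

res$centroids
#> centroid_set: 129 centroids (order 1: 9, order 2: 36, order 3: 84) over 90 features

subset(res$composition, label %in% c("alpha", "beta", "alpha+beta"))
#>    condition      label   n proportion
#> 1       ctrl       beta 647    0.53339
#> 2       ctrl      alpha 229    0.18879
#> 10      ctrl alpha+beta  12    0.00989
#> 15        ko       beta 457    0.37276
#> 16        ko      alpha 327    0.26672
#> 24        ko alpha+beta   9    0.00734
```

Reading this: of the 2678 QC-passing cells the vote removed 230 as doublets
(240 were planted before QC), retained 66 suggestive polyhormonal cells
(mostly `alpha+beta`, the most abundant endocrine pair), and the
composition table recovers the simulated knockout's beta-cell depletion
(53% → 37%) with the alpha fraction rising accordingly. Against the
generator's ground truth this run achieves doublet precision 0.89 / recall
0.93, polyhormonal recall 0.75, and 100% type accuracy on retained
singlets.

With `out_dir = "run"` the pipeline writes `cell_table.tsv`,
`centroids.tsv`, `final_status.tsv`, `composition.tsv`,
`group_comparison.tsv`, `de_genes.tsv` and a `manifest.json` whose
checksums are byte-identical across reruns with the same seed.

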