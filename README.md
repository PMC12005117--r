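# aireclass

Classification and stochasticity analysis of Aire target genes in
thymic epithelial cells.

## The problem

Aire drives the promiscuous expression of thousands of genes — many of
them tissue-restricted antigens — in medullary thymic epithelial cells
(mTECs), but bulk WT-vs-knockout comparisons conflate two different
phenomena. Comparing the primary Aire-expressing single-cell cluster of
WT mice with its counterpart cluster in Aire-KO mice yields a set of
up-regulated genes (**Aire-DEGs**) that splits in two:

* **Aire-driven genes** — expressed only in the Aire-expressing
  cluster, stochastically, in a small fraction (~13%) of its cells;
  essentially uncorrelated with each other except for occasional pairs
  of chromosomal neighbors (median separation ~20 kb) that fire
  together;
* **Aire-enhanced genes** — additionally expressed, Aire-independently,
  in mimetic-cell clusters, where they form coordinated co-expression
  modules whose members are scattered across chromosomes.

`aireclass` implements the computational route to this classification
and the statistics around it:

| stage | functions |
| --- | --- |
| normalization (per-cell log, GeTMM, group z-scores) | `lognormalize`, `getmm`, `group_zscore` |
| statistical kernels | `rank_sum_test`, `auroc`, `adjust_pvalues`, `chi_square_2x2`, `anova_tukey`, `sma_fit`, `perm_z_test` |
| DEG calling, cluster attribution, classing | `two_group_deg`, `extract_aire_degs`, `cluster_marker_stats`, `attribute_genes`, `classify_aire_degs`, `classify_dynamics`, `call_aire_neutral` |
| expressing-cell fraction statistics | `expressing_fraction`, `fraction_table`, `compare_fractions`, `top_quantile_mean` |
| co-expression micro-clusters and genomic geometry | `filter_correlation_genes`, `correlation_matrix`, `affinity_propagation`, `extract_connections`, `connection_stats` |
| cross-dataset cell-to-cluster matching | `select_signatures`, `assign_cells`, `matching_matrix` |
| TF expression–activity correlation with dual permutation nulls | `tf_activity_correlation`, `tf_perm_significance`, `select_characteristic_tfs` |
| bulk contribution and TRA calling | `call_bulk_aire_induced`, `cluster_contribution`, `call_tra` |
| CUT&Tag spike-in scaling and track statistics | `compute_frspike`, `scaling_factors`, `scale_track`, `locus_density`, `tss_profile`, `peak_proximity` |
| synthetic cohorts with recorded truth | `sim_params`, `simulate_tec_dataset`, `build_genome`, `build_design`, `simulate_counts`, `simulate_spike_library`, `simulate_tracks_peaks`, `simulate_tf_activity` |
| orchestration | `run_config`, `run_pipeline`, `classification_benchmark` |

The key decision rule is the four-branch attribution of a gene to
clusters from one-vs-rest significance (Wilcoxon adjusted p < 1e-5) and
z-scores of cluster means: exclusive significance in the top cluster,
or a z-gap > 1 over the runner-up, assigns the top cluster; otherwise
the gene is spread over the positive-z or not-lower-than-significant
clusters. An Aire-DEG attributed solely to the Aire cluster is
Aire-driven; attributed anywhere else, Aire-enhanced.

## Worked example

Everything below runs on a synthetic cohort with known ground truth —
2,900 cells in seven clusters (a WT-only Aire cluster of 500 cells, its
KO-only counterpart, an mTEC-low and a transit-amplifying cluster, and
three mimetic clusters), 1,640 genes of which 500 are Aire-driven, 500
Aire-enhanced, 500 neutral and 140 cluster markers.

```r
library(aireclass)

exp <- simulate_tec_dataset(sim_params(seed = 42))
layer <- exp$layers$lognorm

# 1. Aire-DEGs: WT Aire cluster vs KO counterpart
deg <- two_group_deg(layer, cells_of(exp, "aire", "WT"),
                     cells_of(exp, "aireless"))
aire_degs <- extract_aire_degs(deg)

# 2. attribution over the WT mTEC-high clusters, then classing
high_wt <- exp$cells$genotype == "WT" &
  exp$cells$cluster %in% c("aire", "ta", "m1", "m2", "m3")
ms <- cluster_marker_stats(layer[, high_wt], exp$cells$cluster[high_wt])
attribution <- attribute_genes(ms$means, ms$p_adj, ms$delta)
classes <- classify_aire_degs(attribution, aire_degs, "aire")
table(classes$class)

# 3. stochasticity: expressing-cell fractions in the Aire cluster
driven <- classes$gene[classes$class == "aire_driven"]
ft <- fraction_table(layer, driven, cells_of(exp, "aire", "WT"))
median(ft$fraction)

# 4. co-expression geometry of the two classes (truth labels shown
#    for illustration; the classifier never sees them)
conn_of <- function(genes, cells) {
  genes <- intersect(genes, filter_correlation_genes(exp$counts, cells))
  extract_connections(correlation_matrix(layer, genes, cells), exp$genes)
}
cd <- conn_of(exp$genes$gene_id[exp$genes$truth_class == "aire_driven"],
              c(cells_of(exp, "aire"), cells_of(exp, "aireless")))
ce <- conn_of(exp$genes$gene_id[exp$genes$truth_class == "aire_enhanced"],
              cells_of(exp, c("m1", "m2", "m3")))
connection_stats(cd, ce)
```

Output of the run above:

```
Aire-DEGs: 1018

  aire_driven aire_enhanced          none
          520           498           622

driven precision: 0.962  recall: 1
median expressing fraction: 0.14

driven:   25 connections, 100% intra-chromosomal, median distance 20.2 kb
enhanced: 42250 connections, 80.2% inter-chromosomal
class contingency chi-square p = 1.06e-22
```

Reading it: the blind pipeline recovers every planted Aire-driven gene
(recall 1.0; the 4% "false" positives are the Aire cluster's own
constitutive marker genes, which genuinely satisfy the Aire-driven
definition). The called driven genes fire in a median 14% of
Aire-cluster cells, matching the planted firing probability of 13.1%.
Their rare co-expressed pairs are all chromosomal neighbors (median
20.2 kb apart — these are the gate-sharing adjacent pairs), while the
module-coordinated enhanced genes connect overwhelmingly across
chromosomes; the chi-square on the 2×2 intra/inter contingency
confirms the asymmetry.

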