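# End-to-end recovery benchmark on synthetic cohorts with known truth.

#' Classification recovery benchmark
#'
#' Simulates one cohort per seed under the given parameters, runs the
#' full classification pipeline (DEG extraction, cluster attribution,
#' Aire-driven/enhanced labelling) blind to the truth, and scores the
#' recovery of the Aire-driven class plus the median expressing-cell
#' fraction of the called Aire-driven genes in the Aire cluster.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param params Base [sim_params()]; the seed field is replaced per
#'   run.
#' @param design Cluster design, default [default_design()].
#' @return Data frame per seed: `seed`, `n_aire_degs`, `precision`,
#'   `recall`, `median_fraction`.
#' @export
classification_benchmark <- function(seeds, params = sim_params(),
                                     design = default_design()) {
  out <- lapply(seeds, function(s) {
    params$seed <- s
    exp <- simulate_tec_dataset(params, design = design)
    layer <- exp$layers$lognorm
    aire_cl <- attr(exp$cells, "aire_cluster") %||% "aire"
    ko_cl <- attr(exp$cells, "ko_counterpart") %||% "aireless"
    deg <- two_group_deg(layer, cells_of(exp, aire_cl, "WT"),
                         cells_of(exp, ko_cl))
    degs <- extract_aire_degs(deg)
    high_wt <- exp$cells$genotype == "WT" &
      exp$cells$cluster %in% mtec_high_clusters(exp)
    ms <- cluster_marker_stats(layer[, high_wt, drop = FALSE],
                               exp$cells$cluster[high_wt])
    at <- attribute_genes(ms$means, ms$p_adj, ms$delta)
    cl <- classify_aire_degs(at, degs, aire_cl)
    called <- cl$gene[cl$class == "aire_driven"]
    truth <- exp$genes$gene_id[exp$genes$truth_class == "aire_driven"]
    med_frac <- if (length(called) > 0) {
      stats::median(fraction_table(layer, called,
                                   cells_of(exp, aire_cl, "WT"))$fraction)
    } else NA_real_
    data.frame(seed = s,
               n_aire_degs = length(degs),
               precision = mean(called %in% truth),
               recall = mean(truth %in% called),
               median_fraction = med_frac)
  })
  do.call(rbind, out)
}
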