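# Bulk Aire-induced gene calling, cluster-contribution decomposition,
# and tissue-restricted antigen (TRA) calling.

#' Call bulk Aire-induced genes
#'
#' Genes down-regulated in bulk Aire-KO mTEC-high relative to WT:
#' KO/WT fold change below `fc_max` with FDR below `fdr_max` (both
#' strict).
#'
#' @param bulk Data frame with columns `gene`, `fc_ko_over_wt`, `fdr`.
#' @param fc_max Fold-change ceiling (default 0.5).
#' @param fdr_max FDR ceiling (default 0.05).
#' @return Character vector of gene ids.
#' @export
call_bulk_aire_induced <- function(bulk, fc_max = 0.5, fdr_max = 0.05) {
  req <- c("gene", "fc_ko_over_wt", "fdr")
  if (!all(req %in% names(bulk))) {
    stop("bulk table needs columns gene, fc_ko_over_wt, fdr")
  }
  bulk$gene[bulk$fc_ko_over_wt < fc_max & bulk$fdr < fdr_max]
}

#' Cluster contribution to gene expression
#'
#' The contribution of a cluster to a gene is the product of the
#' cluster's mean expression of that gene and the cluster's relative
#' size within the analyzed population.
#'
#' @param layer Genes x cells normalized matrix.
#' @param clusters Cluster label per cell.
#' @param sizes Named relative cluster sizes summing to 1 over the
#'   cluster set; default: observed cell proportions.
#' @return List: `contribution` (genes x clusters, non-negative),
#'   `top_contributor` per gene, `top_share` (fraction of genes whose
#'   top contributor is each cluster).
#' @export
cluster_contribution <- function(layer, clusters, sizes = NULL) {
  clusters <- factor(clusters)
  if (is.null(sizes)) {
    sizes <- table(clusters) / length(clusters)
    sizes <- stats::setNames(as.numeric(sizes), names(sizes))
  }
  if (!all(levels(clusters) %in% names(sizes))) {
    stop("sizes must name every cluster")
  }
  sizes <- sizes[levels(clusters)]
  if (abs(sum(sizes) - 1) > 1e-8) stop("sizes must sum to 1")
  means <- group_means(layer, clusters)
  contrib <- sweep(means, 2, sizes, `*`)
  top_idx <- max.col(contrib, ties.method = "first")
  top <- colnames(contrib)[top_idx]
  share <- table(factor(top, levels = colnames(contrib))) /
    nrow(contrib)
  list(contribution = contrib,
       top_contributor = stats::setNames(top, rownames(contrib)),
       top_share = stats::setNames(as.numeric(share), colnames(contrib)))
}

#' Call tissue-restricted antigen (TRA) genes
#'
#' A gene is a TRA when it is expressed (value strictly above the
#' threshold) in at least one and at most `max_organs` organs. Genes
#' expressed nowhere are not TRAs.
#'
#' @param organ_table Genes x organs non-negative matrix with gene ids
#'   as row names.
#' @param max_organs Maximum organs for restriction (default 3,
#'   inclusive).
#' @param threshold Scalar, per-gene vector, or `NULL` (default: per
#'   gene, the median of its positive values).
#' @return Character vector of TRA gene ids.
#' @export
call_tra <- function(organ_table, max_organs = 3, threshold = NULL) {
  organ_table <- as.matrix(organ_table)
  if (any(organ_table < 0)) stop("organ table must be non-negative")
  if (is.null(threshold)) {
    threshold <- apply(organ_table, 1, function(v) {
      pos <- v[v > 0]
      if (length(pos) == 0) 0 else stats::median(pos)
    })
  }
  n_organs <- rowSums(organ_table > threshold)
  rownames(organ_table)[n_organs >= 1 & n_organs <= max_organs]
}
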