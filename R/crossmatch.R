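# Cross-dataset cell-to-cluster label transfer via auROC-selected
# signature genes and Pearson correlation to reference cluster profiles.

#' Select per-cluster signature genes
#'
#' For each reference cluster, genes are scored one-vs-rest by auROC and
#' rank-sum p (BH-adjusted over genes); genes with adjusted p below 0.05
#' are ranked by `|AUC - 0.5|` descending and truncated at `top_k`.
#'
#' @param layer Reference genes x cells normalized matrix.
#' @param clusters Cluster label per reference cell (>= 2 clusters).
#' @param top_k Maximum signature size per cluster (default 2000).
#' @param p_max Adjusted-p cut for membership (default 0.05).
#' @param min_cells Clusters smaller than this are skipped with a
#'   warning (default 3).
#' @return Named list per cluster: data frame `gene`, `auc`, `p_adj`,
#'   ordered by decreasing `|auc - 0.5|`.
#' @export
select_signatures <- function(layer, clusters, top_k = 2000,
                              p_max = 0.05, min_cells = 3) {
  clusters <- factor(clusters)
  if (nlevels(clusters) < 2L) stop("need at least two reference clusters")
  out <- list()
  for (cl in levels(clusters)) {
    a <- which(clusters == cl); b <- which(clusters != cl)
    if (length(a) < min_cells) {
      warning(sprintf("cluster %s has fewer than %d cells; skipped",
                      cl, min_cells))
      next
    }
    rs <- rank_sum_rows(layer, a, b)
    # AUC from the same rank sums: U = W - n1(n1+1)/2
    n1 <- length(a); n2 <- length(b)
    auc <- (rs$w - n1 * (n1 + 1) / 2) / (n1 * n2)
    p_adj <- adjust_pvalues(rs$p, "bh")
    keep <- which(p_adj < p_max)
    ord <- keep[order(abs(auc[keep] - 0.5), decreasing = TRUE)]
    ord <- ord[seq_len(min(top_k, length(ord)))]
    out[[cl]] <- data.frame(gene = rownames(layer)[ord],
                            auc = auc[ord], p_adj = p_adj[ord],
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Assign query cells to reference clusters
#'
#' Each query cell is correlated (Pearson) with every reference
#' cluster's mean profile over the union of the signature genes and
#' assigned to the best-correlated cluster; cells whose best correlation
#' is at or below `min_r` stay unassigned. Ties are broken toward the
#' first reference cluster in order.
#'
#' @param query_layer Query genes x cells normalized matrix.
#' @param ref_layer Reference genes x cells normalized matrix.
#' @param ref_clusters Cluster label per reference cell.
#' @param signatures Output of [select_signatures()].
#' @param min_r Assignment threshold: unassigned when best r <= `min_r`
#'   (default 0.2).
#' @return Data frame per query cell: `cell`, `best_cluster`
#'   (`"unassigned"` below threshold), `r`.
#' @export
assign_cells <- function(query_layer, ref_layer, ref_clusters,
                         signatures, min_r = 0.2) {
  sig_genes <- unique(unlist(lapply(signatures, `[[`, "gene")))
  shared <- intersect(sig_genes, rownames(query_layer))
  if (length(shared) == 0L) {
    stop("no signature genes present in the query")
  }
  if (length(shared) < length(sig_genes)) {
    warning(sprintf("%d signature gene(s) absent from the query dropped",
                    length(sig_genes) - length(shared)))
  }
  ref_means <- group_means(ref_layer[shared, , drop = FALSE],
                           factor(ref_clusters))
  q <- query_layer[shared, , drop = FALSE]
  r_mat <- stats::cor(q, ref_means)   # cells x clusters
  r_mat[is.na(r_mat)] <- -1           # constant query cells never assign
  best <- max.col(r_mat, ties.method = "first")
  best_r <- r_mat[cbind(seq_len(nrow(r_mat)), best)]
  cluster <- colnames(ref_means)[best]
  cluster[best_r <= min_r] <- "unassigned"
  data.frame(cell = colnames(query_layer), best_cluster = cluster,
             r = best_r, row.names = NULL, stringsAsFactors = FALSE)
}

#' Query-by-reference matching proportion matrix
#'
#' @param assignments Output of [assign_cells()].
#' @param query_clusters Cluster label per query cell (same order as the
#'   assignment table).
#' @return Matrix, rows = query clusters, columns = reference clusters
#'   plus `unassigned`; each non-empty row sums to 1.
#' @export
matching_matrix <- function(assignments, query_clusters) {
  query_clusters <- as.factor(query_clusters)
  ref_levels <- sort(setdiff(unique(assignments$best_cluster),
                             "unassigned"))
  lv <- c(ref_levels, "unassigned")
  tab <- table(query_clusters,
               factor(assignments$best_cluster, levels = lv))
  prop <- prop.table(tab, margin = 1)
  out <- matrix(as.numeric(prop), nrow = nrow(prop),
                dimnames = dimnames(prop))
  out[rowSums(tab) == 0, ] <- NA_real_
  out
}
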