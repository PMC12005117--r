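# Per-gene expressing-cell fraction statistics and high-expression
# comparisons.

#' Expressing-cell fraction of a gene
#'
#' A cell counts as expressing when its normalized value exceeds
#' `frac` times the `q`-th quantile (linear interpolation) of the gene's
#' values across the analyzed cells. The fraction is the share of
#' expressing cells among those cells.
#'
#' @param values Normalized expression values of one gene across the
#'   analyzed cells (at least one cell).
#' @param q Quantile defining the reference high expression
#'   (default 0.975).
#' @param frac Fraction of the reference quantile acting as the
#'   expression threshold (default 0.25).
#' @return List with `threshold` and `fraction`.
#' @export
expressing_fraction <- function(values, q = 0.975, frac = 0.25) {
  if (length(values) < 1L) stop("need at least one cell")
  thr <- frac * stats::quantile(values, q, names = FALSE, type = 7)
  list(threshold = thr, fraction = mean(values > thr))
}

#' Expressing fractions for a gene set within a cluster
#'
#' The reference quantile is computed per gene across all cells in
#' `quantile_cells` (the populations under comparison); the fraction is
#' evaluated within `cluster_cells`.
#'
#' @param layer Genes x cells normalized matrix.
#' @param genes Gene ids (rows).
#' @param cluster_cells Cell ids of the queried cluster.
#' @param quantile_cells Cell ids over which the quantile is taken;
#'   defaults to `cluster_cells`.
#' @param q,frac See [expressing_fraction()].
#' @return Data frame: `gene`, `threshold`, `fraction`.
#' @export
fraction_table <- function(layer, genes, cluster_cells,
                           quantile_cells = cluster_cells,
                           q = 0.975, frac = 0.25) {
  rows <- match(genes, rownames(layer))
  if (anyNA(rows)) stop("unknown gene ids")
  qc <- match(quantile_cells, colnames(layer))
  cc <- match(cluster_cells, colnames(layer))
  if (anyNA(qc) || anyNA(cc)) stop("unknown cell ids")
  thr <- frac * apply(layer[rows, qc, drop = FALSE], 1,
                      stats::quantile, probs = q, names = FALSE, type = 7)
  fr <- rowMeans(layer[rows, cc, drop = FALSE] > thr)
  data.frame(gene = genes, threshold = thr, fraction = fr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare expressing fractions between gene groups
#'
#' One-way ANOVA with Tukey HSD on per-gene expressing fractions grouped
#' by the cluster the genes are attributed to.
#'
#' @param fractions Named list of numeric fraction vectors, one per
#'   group (at least two groups of at least two genes).
#' @return As [anova_tukey()].
#' @export
compare_fractions <- function(fractions) {
  anova_tukey(fractions)
}

#' Mean over the top expression quantile
#'
#' Mean of the `ceiling(top_frac * n)` largest values; with ten cells
#' and the default 5% this is the single maximum.
#'
#' @param values Numeric vector (at least one value).
#' @param top_frac Fraction of top cells (default 0.05).
#' @return Mean of the top cells.
#' @export
top_quantile_mean <- function(values, top_frac = 0.05) {
  if (length(values) < 1L) stop("need at least one cell")
  k <- ceiling(top_frac * length(values))
  mean(sort(values, decreasing = TRUE)[seq_len(k)])
}
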