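# Normalization layers: per-cell log-normalization, gene-length corrected
# TMM (GeTMM), and group-level z-score standardization.

#' Per-cell log-normalization
#'
#' Each cell's counts are divided by the cell total, multiplied by
#' `scale`, and natural-log transformed with a pseudocount of 1:
#' `ln(1 + scale * count / total)`. Cells with zero total map to zeros.
#'
#' @param counts Non-negative genes x cells matrix.
#' @param scale Size-factor target, default 10000.
#' @return Matrix of the same shape.
#' @export
lognormalize <- function(counts, scale = 10000) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  div <- ifelse(totals > 0, totals, 1)
  out <- log1p(sweep(counts, 2, scale / div, `*`))
  dimnames(out) <- dimnames(counts)
  out
}

#' Gene-length corrected TMM normalization (GeTMM)
#'
#' Counts are converted to reads per kilobase (RPK), trimmed-mean-of-M
#' scaling factors are computed on the RPK matrix (TMM defaults: 30% M
#' trim, 5% A trim, reference sample = the one whose upper quartile is
#' closest to the mean upper quartile), and counts-per-million are taken
#' on the scaled RPK. Genes with zero counts in all samples do not enter
#' the factor computation. The TMM step is delegated to
#' [edgeR::calcNormFactors()].
#'
#' @param counts Genes x samples matrix of raw counts.
#' @param gene_lengths Positive gene lengths in bp, one per row.
#' @param log2_transform Return `log2(GeTMM + 1)` instead of GeTMM.
#' @return Normalized genes x samples matrix.
#' @export
getmm <- function(counts, gene_lengths, log2_transform = FALSE) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts)) {
    stop("need one gene length per row")
  }
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(colSums(counts) == 0)) stop("zero-library sample")
  rpk <- counts / (gene_lengths / 1000)
  dge <- edgeR::DGEList(counts = rpk)
  # unweighted trimmed mean: factors depend on relative profiles only,
  # so rescaling one sample's counts leaves its normalized profile fixed
  dge <- edgeR::calcNormFactors(dge, method = "TMM", doWeighting = FALSE)
  out <- edgeR::cpm(dge, normalized.lib.sizes = TRUE, log = FALSE)
  if (log2_transform) out <- log2(out + 1)
  dimnames(out) <- dimnames(counts)
  out
}

#' Group-level z-score standardization
#'
#' Per gene, group means are computed on the supplied layer and
#' standardized across groups: `(mean_g - mean(means)) / sd(means)`.
#' Genes whose group means are all equal map to zeros.
#'
#' @param layer Genes x cells matrix (typically log-normalized values).
#' @param groups Group label per cell (coerced to factor); at least two
#'   distinct groups.
#' @return Genes x groups matrix of z-scores.
#' @export
group_zscore <- function(layer, groups) {
  layer <- as.matrix(layer)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (length(groups) != ncol(layer)) stop("one group label per cell")
  means <- group_means(layer, groups)
  mu <- rowMeans(means)
  sdv <- apply(means, 1, stats::sd)
  z <- (means - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

# Row-wise means per group; genes x groups matrix.
group_means <- function(layer, groups) {
  groups <- factor(groups)
  out <- vapply(levels(groups),
                function(g) rowMeans(layer[, groups == g, drop = FALSE]),
                numeric(nrow(layer)))
  out <- matrix(out, nrow = nrow(layer),
                dimnames = list(rownames(layer), levels(groups)))
  out
}
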