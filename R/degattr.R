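# Differential expression, the gene-to-cluster attribution rule, and the
# Aire-driven / Aire-enhanced classification of Aire-DEGs.

# Row-wise rank-sum statistics for a matrix: W (rank sum of group A),
# tie-corrected continuity-corrected normal p per gene.
rank_sum_rows <- function(layer, a_idx, b_idx) {
  n1 <- length(a_idx); n2 <- length(b_idx); n <- n1 + n2
  x <- layer[, c(a_idx, b_idx), drop = FALSE]
  stat <- t(apply(x, 1, function(v) {
    r <- rank(v)
    tt <- table(v)
    c(sum(r[seq_len(n1)]), sum(tt^3 - tt))
  }))
  w <- stat[, 1]
  mu <- n1 * (n + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - stat[, 2] / (n * (n - 1)))
  z <- ifelse(sigma2 > 0,
              (w - mu - sign(w - mu) * 0.5) / sqrt(pmax(sigma2, 1e-300)),
              0)
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  p[sigma2 <= 0] <- 1
  list(w = w, p = p)
}

#' Two-group differential expression
#'
#' Per-gene Wilcoxon rank-sum test on a log-normalized layer with
#' Bonferroni correction over the tested genes. Genes expressed (value
#' greater than 0) in fewer than `min_frac` of cells in *both* groups are
#' excluded from testing. The log fold change is the natural log of the
#' ratio of per-group means of `expm1(value)`, each shifted by 1.
#'
#' @param layer Genes x cells log-normalized matrix with cell ids as
#'   column names.
#' @param cells_a,cells_b Disjoint, non-empty cell-id vectors.
#' @param min_frac Expression-fraction floor for testing (default 0.05).
#' @return Data frame per gene: `gene`, `log_fc`, `p`, `p_adj`,
#'   `frac_a`, `frac_b`, `excluded`.
#' @export
two_group_deg <- function(layer, cells_a, cells_b, min_frac = 0.05) {
  a_idx <- match(cells_a, colnames(layer))
  b_idx <- match(cells_b, colnames(layer))
  if (anyNA(a_idx) || anyNA(b_idx)) stop("unknown cell ids")
  if (length(a_idx) == 0L || length(b_idx) == 0L) {
    stop("both cell sets must be non-empty")
  }
  if (length(intersect(a_idx, b_idx)) > 0L) {
    stop("cell sets must be disjoint")
  }
  frac_a <- rowMeans(layer[, a_idx, drop = FALSE] > 0)
  frac_b <- rowMeans(layer[, b_idx, drop = FALSE] > 0)
  excluded <- frac_a < min_frac & frac_b < min_frac
  mean_a <- rowMeans(expm1(layer[, a_idx, drop = FALSE]))
  mean_b <- rowMeans(expm1(layer[, b_idx, drop = FALSE]))
  log_fc <- log((mean_a + 1) / (mean_b + 1))
  p <- rep(NA_real_, nrow(layer))
  p_adj <- rep(NA_real_, nrow(layer))
  if (any(!excluded)) {
    rs <- rank_sum_rows(layer[!excluded, , drop = FALSE], a_idx, b_idx)
    p[!excluded] <- rs$p
    p_adj[!excluded] <- adjust_pvalues(rs$p, "bonferroni",
                                       m = sum(!excluded))
  }
  data.frame(gene = rownames(layer), log_fc = log_fc, p = p,
             p_adj = p_adj, frac_a = frac_a, frac_b = frac_b,
             excluded = excluded, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Extract Aire-DEGs from a DEG table
#'
#' Genes significantly up-regulated in the Aire-expressing cluster of WT
#' relative to its KO counterpart: adjusted p below `p_max` with a
#' positive log fold change.
#'
#' @param deg_table Output of [two_group_deg()] comparing WT Aire cluster
#'   (group A) against the KO counterpart (group B).
#' @param p_max Adjusted-p threshold (default 0.05).
#' @return Character vector of gene ids.
#' @export
extract_aire_degs <- function(deg_table, p_max = 0.05) {
  sel <- !deg_table$excluded & !is.na(deg_table$p_adj) &
    deg_table$p_adj < p_max & deg_table$log_fc > 0
  deg_table$gene[sel]
}

#' One-vs-rest cluster marker statistics
#'
#' For every cluster, each gene is tested by the rank-sum test against
#' all remaining cells, with Bonferroni adjustment over genes within the
#' cluster. A cluster counts as significantly *up* only when the
#' cluster's mean exceeds the rest mean.
#'
#' @param layer Genes x cells log-normalized matrix.
#' @param clusters Cluster label per cell.
#' @return List: `p_adj` and `delta` (cluster mean minus rest mean),
#'   both genes x clusters, and `means` (genes x clusters group means).
#' @export
cluster_marker_stats <- function(layer, clusters) {
  clusters <- factor(clusters)
  if (nlevels(clusters) < 2L) stop("need at least two clusters")
  means <- group_means(layer, clusters)
  p_adj <- delta <- matrix(NA_real_, nrow(layer), nlevels(clusters),
                           dimnames = list(rownames(layer),
                                           levels(clusters)))
  for (cl in levels(clusters)) {
    a <- which(clusters == cl); b <- which(clusters != cl)
    rs <- rank_sum_rows(layer, a, b)
    p_adj[, cl] <- adjust_pvalues(rs$p, "bonferroni", m = nrow(layer))
    delta[, cl] <- means[, cl] - rowMeans(layer[, b, drop = FALSE])
  }
  list(p_adj = p_adj, delta = delta, means = means)
}

#' Attribute genes to clusters
#'
#' Implements the four-branch attribution rule on per-gene cluster means
#' and one-vs-rest significance calls:
#' \describe{
#'   \item{exclusive}{significantly up only in the cluster with the
#'     highest mean: assign that cluster.}
#'   \item{zgap}{the z-score of the top cluster exceeds the second
#'     highest by more than `z_gap`: assign the top cluster.}
#'   \item{multi_soft}{no cluster significant: assign every cluster with
#'     a positive z-score.}
#'   \item{multi_sig}{several clusters significant without a sufficient
#'     gap: assign every cluster whose mean is not lower than the lowest
#'     mean among the significant clusters.}
#' }
#' Z-scores standardize the cluster means per gene across clusters.
#'
#' @param means Genes x clusters matrix of cluster mean expression.
#' @param p_adj Genes x clusters adjusted one-vs-rest p-values.
#' @param delta Genes x clusters cluster-minus-rest mean differences
#'   (used to restrict significance to up-regulation).
#' @param p_cut Significance threshold, default `1e-5`.
#' @param z_gap Z-score gap for sole assignment, default 1.
#' @return Data frame per gene: `gene`, `top_cluster`, `branch`,
#'   `assigned` (comma-joined cluster names).
#' @export
attribute_genes <- function(means, p_adj, delta = NULL, p_cut = 1e-5,
                            z_gap = 1) {
  if (ncol(means) < 2L) stop("need at least two clusters")
  cl_names <- colnames(means)
  mu <- rowMeans(means)
  sdv <- apply(means, 1, stats::sd)
  z <- (means - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  sig <- !is.na(p_adj) & p_adj < p_cut
  if (!is.null(delta)) sig <- sig & delta > 0
  out <- data.frame(gene = rownames(means),
                    top_cluster = NA_character_,
                    branch = NA_character_,
                    assigned = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(means))) {
    ord <- order(means[i, ], decreasing = TRUE)
    top <- cl_names[ord[1]]
    out$top_cluster[i] <- top
    sig_i <- cl_names[sig[i, ]]
    zi <- z[i, ]
    gap <- zi[ord[1]] - zi[ord[2]]
    if (length(sig_i) == 1L && sig_i == top) {
      out$branch[i] <- "exclusive"
      assigned <- top
    } else if (gap > z_gap) {
      out$branch[i] <- "zgap"
      assigned <- top
    } else if (length(sig_i) == 0L) {
      out$branch[i] <- "multi_soft"
      assigned <- cl_names[zi > 0]
    } else {
      out$branch[i] <- "multi_sig"
      floor_mean <- min(means[i, sig_i])
      assigned <- cl_names[means[i, ] >= floor_mean]
    }
    out$assigned[i] <- paste(assigned, collapse = ",")
  }
  out
}

#' Split an assignment string into cluster names
#' @param assigned Comma-joined cluster string from [attribute_genes()].
#' @return Character vector (possibly empty).
#' @export
assigned_clusters <- function(assigned) {
  if (is.na(assigned) || assigned == "") return(character())
  strsplit(assigned, ",", fixed = TRUE)[[1]]
}

#' Classify Aire-DEGs into Aire-driven and Aire-enhanced
#'
#' An Aire-DEG attributed solely to the Aire-expressing cluster is
#' Aire-driven; an Aire-DEG attributed to any other cluster is
#' Aire-enhanced; genes outside the Aire-DEG set are `none`.
#'
#' @param attribution Output of [attribute_genes()].
#' @param aire_degs Character vector of Aire-DEG gene ids.
#' @param aire_cluster Name of the Aire-expressing cluster.
#' @return Data frame per gene: `gene`, `class`.
#' @export
classify_aire_degs <- function(attribution, aire_degs, aire_cluster) {
  cls <- rep("none", nrow(attribution))
  in_set <- attribution$gene %in% aire_degs
  for (i in which(in_set)) {
    asg <- assigned_clusters(attribution$assigned[i])
    if (length(asg) == 0L) {
      warning(sprintf("Aire-DEG %s is unattributed; labelled none",
                      attribution$gene[i]))
    } else if (length(asg) == 1L && asg == aire_cluster) {
      cls[i] <- "aire_driven"
    } else if (any(asg != aire_cluster)) {
      cls[i] <- "aire_enhanced"
    }
  }
  data.frame(gene = attribution$gene, class = cls,
             stringsAsFactors = FALSE)
}

#' Expression dynamics along the maturation path
#'
#' Compares the mean expression in the terminal (Aire-expressing)
#' cluster against the initial (mTEC-low) cluster of a maturation path;
#' genes with a higher terminal mean are `mtec_high_up`, otherwise
#' `mtec_high_down`. Exact ties are labelled down and flagged.
#'
#' @param layer Genes x cells log-normalized matrix.
#' @param clusters Cluster label per cell.
#' @param path Character vector of cluster names from immature to the
#'   Aire-expressing end; only the two endpoints enter the rule.
#' @return Data frame per gene: `gene`, `dynamics`, `tie`.
#' @export
classify_dynamics <- function(layer, clusters, path) {
  stopifnot(length(path) >= 2L)
  lo <- which(clusters == path[1])
  hi <- which(clusters == path[length(path)])
  if (length(lo) == 0L || length(hi) == 0L) {
    stop("empty cluster on the maturation path")
  }
  m_lo <- rowMeans(layer[, lo, drop = FALSE])
  m_hi <- rowMeans(layer[, hi, drop = FALSE])
  data.frame(gene = rownames(layer),
             dynamics = ifelse(m_hi > m_lo, "mtec_high_up",
                               "mtec_high_down"),
             tie = m_hi == m_lo,
             stringsAsFactors = FALSE)
}

#' Call Aire-neutral genes
#'
#' Genes expressed comparably between WT and Aire-KO in both bulk
#' (absolute bulk log2 fold change below `bulk_lfc_max` with FDR above
#' `bulk_fdr_min`) and single-cell data (adjusted p at or above
#' `sc_p_min` in the WT-Aire versus KO-counterpart comparison).
#'
#' @param sc_deg Single-cell DEG table from [two_group_deg()].
#' @param bulk Data frame with columns `gene`, `log2_fc`, `fdr`.
#' @param bulk_lfc_max,bulk_fdr_min,sc_p_min Thresholds (defaults 0.2,
#'   0.05, 1e-5).
#' @return Character vector of Aire-neutral gene ids.
#' @export
call_aire_neutral <- function(sc_deg, bulk, bulk_lfc_max = 0.2,
                              bulk_fdr_min = 0.05, sc_p_min = 1e-5) {
  if (!all(c("gene", "log2_fc", "fdr") %in% names(bulk))) {
    stop("bulk table needs columns gene, log2_fc, fdr")
  }
  shared <- intersect(sc_deg$gene, bulk$gene)
  b <- bulk[match(shared, bulk$gene), ]
  s <- sc_deg[match(shared, sc_deg$gene), ]
  ok_bulk <- abs(b$log2_fc) < bulk_lfc_max & b$fdr > bulk_fdr_min
  ok_sc <- is.na(s$p_adj) | s$p_adj >= sc_p_min
  shared[ok_bulk & ok_sc]
}
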