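# Correlation between TF transcript abundance and motif activity with a
# dual permutation null (cluster-label shuffling and TF-identity
# substitution); the reported p is the less significant of the two.

#' TF expression-activity correlation over cluster means
#'
#' Pearson correlation between the vector of per-cluster mean
#' expressions of a TF gene and the per-cluster mean motif activities of
#' the corresponding motif.
#'
#' @param expr_layer Genes x cells normalized expression matrix.
#' @param activity TFs x cells motif-activity matrix (TF rows named by
#'   their gene).
#' @param clusters Cluster label per cell (>= 3 clusters).
#' @param tfs TFs to evaluate; default all activity rows present in the
#'   expression matrix.
#' @return Data frame `tf`, `r` (NA with a warning for constant
#'   vectors).
#' @export
tf_activity_correlation <- function(expr_layer, activity, clusters,
                                    tfs = NULL) {
  clusters <- factor(clusters)
  if (nlevels(clusters) < 3L) stop("need at least three clusters")
  if (is.null(tfs)) {
    tfs <- intersect(rownames(activity), rownames(expr_layer))
  }
  if (length(tfs) == 0L) stop("no TFs present in both matrices")
  em <- group_means(expr_layer[tfs, , drop = FALSE], clusters)
  am <- group_means(activity[tfs, , drop = FALSE], clusters)
  r <- vapply(seq_along(tfs), function(i) {
    if (stats::sd(em[i, ]) == 0 || stats::sd(am[i, ]) == 0) {
      warning(sprintf("constant cluster means for %s; r undefined",
                      tfs[i]))
      return(NA_real_)
    }
    stats::cor(em[i, ], am[i, ])
  }, numeric(1))
  data.frame(tf = tfs, r = r, row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation significance of TF expression-activity correlations
#'
#' Two nulls per TF: (1) shuffle the cluster labels of the TF's
#' cluster-mean activity vector; (2) substitute the activity vectors of
#' `n_perm` other TFs sampled without replacement (with replacement when
#' fewer are available). Each null yields a z-test p against the
#' permuted correlation distribution; the reported `p_final` is the
#' maximum (least significant) of the two.
#'
#' @param expr_layer,activity,clusters As
#'   [tf_activity_correlation()].
#' @param tfs TFs to evaluate; default all shared TFs.
#' @param n_perm Permutations per null (default 100).
#' @param seed Random seed.
#' @return Data frame `tf`, `r`, `p_label`, `p_tf`, `p_final`,
#'   `degenerate`.
#' @export
tf_perm_significance <- function(expr_layer, activity, clusters,
                                 tfs = NULL, n_perm = 100, seed = 1L) {
  if (n_perm < 2L) stop("need at least two permutations")
  set.seed(seed)
  clusters <- factor(clusters)
  if (is.null(tfs)) {
    tfs <- intersect(rownames(activity), rownames(expr_layer))
  }
  em <- group_means(expr_layer[tfs, , drop = FALSE], clusters)
  am_all <- group_means(activity, clusters)
  am <- am_all[tfs, , drop = FALSE]
  k <- nlevels(clusters)
  out <- data.frame(tf = tfs, r = NA_real_, p_label = NA_real_,
                    p_tf = NA_real_, p_final = NA_real_,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  all_tf_pool <- rownames(am_all)
  for (i in seq_along(tfs)) {
    e <- em[i, ]; a <- am[i, ]
    if (stats::sd(e) == 0 || stats::sd(a) == 0) {
      out$p_label[i] <- out$p_tf[i] <- out$p_final[i] <- 1
      out$degenerate[i] <- TRUE
      next
    }
    r_obs <- stats::cor(e, a)
    out$r[i] <- r_obs
    perm_label <- vapply(seq_len(n_perm), function(j) {
      stats::cor(e, a[sample.int(k)])
    }, numeric(1))
    t1 <- perm_z_test(r_obs, perm_label)
    pool <- setdiff(all_tf_pool, tfs[i])
    pick <- if (length(pool) >= n_perm) sample(pool, n_perm)
            else sample(pool, n_perm, replace = TRUE)
    perm_tf <- vapply(pick, function(other) {
      v <- am_all[other, ]
      if (stats::sd(v) == 0) return(0)
      stats::cor(e, v)
    }, numeric(1))
    t2 <- perm_z_test(r_obs, perm_tf)
    out$p_label[i] <- t1$p
    out$p_tf[i] <- t2$p
    out$p_final[i] <- max(t1$p, t2$p)
    out$degenerate[i] <- isTRUE(t1$degenerate) || isTRUE(t2$degenerate)
  }
  out
}

#' Select the characteristic TF per cluster
#'
#' Among TFs with a significant expression-activity correlation
#' (`|r| > r_min`), TFs qualify for a cluster when their one-vs-rest
#' expression AUC exceeds `auc_min` (strictly); the top-AUC TF is
#' reported per cluster.
#'
#' @param tf_table Data frame with `tf` and `r` (e.g. from
#'   [tf_perm_significance()]).
#' @param expr_layer Genes x cells normalized expression matrix.
#' @param clusters Cluster label per cell.
#' @param r_min Correlation magnitude threshold (strict; default 0.4).
#' @param auc_min AUC threshold (strict; default 0.75).
#' @return Data frame per cluster: `cluster`, `tf` (NA when no TF
#'   qualifies), `auc`.
#' @export
select_characteristic_tfs <- function(tf_table, expr_layer, clusters,
                                      r_min = 0.4, auc_min = 0.75) {
  clusters <- factor(clusters)
  cand <- tf_table$tf[!is.na(tf_table$r) & abs(tf_table$r) > r_min]
  cand <- intersect(cand, rownames(expr_layer))
  out <- data.frame(cluster = levels(clusters), tf = NA_character_,
                    auc = NA_real_, stringsAsFactors = FALSE)
  if (length(cand) == 0L) return(out)
  for (ci in seq_along(levels(clusters))) {
    cl <- levels(clusters)[ci]
    a <- which(clusters == cl); b <- which(clusters != cl)
    aucs <- vapply(cand, function(tf) {
      auroc(expr_layer[tf, a], expr_layer[tf, b])
    }, numeric(1))
    ok <- aucs > auc_min
    if (any(ok)) {
      best <- which.max(ifelse(ok, aucs, -Inf))
      out$tf[ci] <- cand[best]
      out$auc[ci] <- aucs[best]
    }
  }
  out
}
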