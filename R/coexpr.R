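# Gene-gene co-expression structure: correlation matrices, affinity
# propagation micro-clusters, high-correlation connections and their
# genomic-position statistics.

#' Filter genes for correlation analysis
#'
#' Keeps genes whose raw count is at least `min_reads` in at least
#' `min_cells` of the selected cells.
#'
#' @param counts Raw genes x cells count matrix.
#' @param cells Cell ids defining the analyzed population.
#' @param min_reads,min_cells Thresholds (defaults 5 and 5; both
#'   inclusive).
#' @return Character vector of gene ids passing the filter.
#' @export
filter_correlation_genes <- function(counts, cells,
                                     min_reads = 5, min_cells = 5) {
  idx <- match(cells, colnames(counts))
  if (anyNA(idx)) stop("unknown cell ids")
  keep <- rowSums(counts[, idx, drop = FALSE] >= min_reads) >= min_cells
  rownames(counts)[keep]
}

#' Gene-gene Pearson correlation matrix
#'
#' @param layer Genes x cells normalized matrix.
#' @param genes Gene ids (rows) to correlate.
#' @param cells Cell ids (at least 3).
#' @return Symmetric correlation matrix over the non-constant genes;
#'   constant genes are dropped with a warning.
#' @export
correlation_matrix <- function(layer, genes, cells) {
  rows <- match(genes, rownames(layer))
  cols <- match(cells, colnames(layer))
  if (anyNA(rows) || anyNA(cols)) stop("unknown gene or cell ids")
  if (length(cols) < 3L) stop("need at least three cells")
  x <- t(layer[rows, cols, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant gene(s) dropped", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
  }
  stats::cor(x)
}

#' Affinity propagation clustering
#'
#' Standard responsibility/availability message passing on a similarity
#' matrix (Frey-Dueck updates with damping). The preference (self
#' similarity) defaults to the median off-diagonal similarity, so the
#' number of clusters is not fixed in advance. Exemplars are the points
#' whose summed responsibility and availability diagonal is positive at
#' convergence; every point is assigned to the exemplar it is most
#' similar to.
#'
#' @param s Square similarity matrix (larger = more similar).
#' @param damping Damping factor in `[0.5, 1)`, default 0.9.
#' @param max_iter Maximum iterations, default 1000.
#' @param conv_window Iterations the exemplar set must stay unchanged to
#'   declare convergence, default 100.
#' @param preference Scalar or per-point preference; default median of
#'   off-diagonal similarities.
#' @return List: `exemplar` (exemplar id per point), `clusters` (named
#'   list of member ids per exemplar), `net_similarity`, `converged`,
#'   `iterations`.
#' @export
affinity_propagation <- function(s, damping = 0.9, max_iter = 1000,
                                 conv_window = 100, preference = NULL) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (n != ncol(s)) stop("similarity matrix must be square")
  ids <- rownames(s)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1L) {
    return(list(exemplar = stats::setNames(ids, ids),
                clusters = stats::setNames(list(ids), ids),
                net_similarity = if (is.null(preference))
                  0 else preference[1],
                converged = TRUE, iterations = 0L))
  }
  if (is.null(preference)) {
    preference <- stats::median(s[row(s) != col(s)])
  }
  diag(s) <- preference
  # tiny deterministic jitter removes degenerate ties (seeded locally so
  # the caller's RNG stream is untouched)
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(42)
  s <- s + s * 1e-12 * matrix(stats::rnorm(n * n), n, n)

  # net similarity of an exemplar index set under the jittered s
  net_of <- function(ex_idx) {
    assign_idx <- ex_idx[max.col(s[, ex_idx, drop = FALSE],
                                 ties.method = "first")]
    assign_idx[ex_idx] <- ex_idx
    sum(s[cbind(seq_len(n), assign_idx)])
  }

  r <- a <- matrix(0, n, n)
  last_ex <- rep(FALSE, n)
  best_ex <- NULL
  best_net <- -Inf
  stable <- 0L
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    as_ <- a + s
    max1_idx <- max.col(as_, ties.method = "first")
    max1 <- as_[cbind(seq_len(n), max1_idx)]
    as2 <- as_
    as2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- as2[cbind(seq_len(n), max.col(as2, ties.method = "first"))]
    rnew <- s - max1
    rnew[cbind(seq_len(n), max1_idx)] <- s[cbind(seq_len(n), max1_idx)] -
      max2
    r <- damping * r + (1 - damping) * rnew
    # availabilities
    rp <- pmax(r, 0)
    diag(rp) <- diag(r)
    colsums <- colSums(rp)
    anew <- matrix(colsums, n, n, byrow = TRUE) - rp
    diag_a <- colsums - diag(r)
    anew <- pmin(anew, 0)
    diag(anew) <- diag_a
    a <- damping * a + (1 - damping) * anew
    ex <- (diag(r) + diag(a)) > 0
    if (identical(ex, last_ex) && any(ex)) {
      stable <- stable + 1L
      if (stable >= conv_window) { converged <- TRUE; break }
    } else {
      stable <- 0L
      # candidate exemplar set changed: score it and keep the best
      if (any(ex)) {
        cand <- net_of(which(ex))
        if (cand > best_net) { best_net <- cand; best_ex <- which(ex) }
      }
    }
    last_ex <- ex
  }
  ex_idx <- which((diag(r) + diag(a)) > 0)
  if (length(ex_idx) == 0L) {
    ex_idx <- which.max(diag(r) + diag(a))
  }
  # keep the best-scoring iterate (identical to the converged set on
  # clean convergence)
  if (!is.null(best_ex) && best_net > net_of(ex_idx)) ex_idx <- best_ex
  assign_idx <- ex_idx[max.col(s[, ex_idx, drop = FALSE],
                               ties.method = "first")]
  assign_idx[ex_idx] <- ex_idx
  net <- sum(s[cbind(seq_len(n), assign_idx)])
  exemplar <- stats::setNames(ids[assign_idx], ids)
  clusters <- split(ids, ids[assign_idx])
  list(exemplar = exemplar, clusters = clusters, net_similarity = net,
       converged = converged, iterations = it)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
}

#' Exhaustive exemplar search (oracle)
#'
#' Maximizes the net similarity over all non-empty exemplar subsets;
#' feasible only for small instances. Used as the independent optimum
#' reference for [affinity_propagation()].
#'
#' @param s Square similarity matrix.
#' @param preference Scalar preference; default median off-diagonal.
#' @return List with `net_similarity` and the optimal `exemplars`
#'   (indices).
#' @export
exhaustive_exemplar_search <- function(s, preference = NULL) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (is.null(preference)) {
    preference <- stats::median(s[row(s) != col(s)])
  }
  diag(s) <- preference
  best <- -Inf; best_set <- NULL
  for (mask in seq_len(2^n - 1)) {
    set <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    val <- sum(diag(s)[set])
    rest <- setdiff(seq_len(n), set)
    if (length(rest) > 0) {
      val <- val + sum(apply(s[rest, set, drop = FALSE], 1, max))
    }
    if (val > best) { best <- val; best_set <- set }
  }
  list(net_similarity = best, exemplars = best_set)
}

#' Extract high-correlation connections
#'
#' Unordered unique gene pairs with Pearson correlation strictly above
#' `threshold`, annotated with chromosome identity and TSS-to-TSS
#' distance.
#'
#' @param cor_mat Symmetric gene-gene correlation matrix.
#' @param gene_meta Gene table with `gene_id`, `chrom`, `tss`.
#' @param threshold Correlation threshold (strict; default 0.6).
#' @return Data frame: `gene_a`, `gene_b`, `r`, `same_chromosome`,
#'   `distance_bp` (NA across chromosomes).
#' @export
extract_connections <- function(cor_mat, gene_meta, threshold = 0.6) {
  genes <- rownames(cor_mat)
  if (!all(genes %in% gene_meta$gene_id)) {
    stop("missing gene annotation for correlated genes")
  }
  idx <- which(upper.tri(cor_mat) & cor_mat > threshold, arr.ind = TRUE)
  ga <- genes[idx[, 1]]; gb <- genes[idx[, 2]]
  ma <- match(ga, gene_meta$gene_id); mb <- match(gb, gene_meta$gene_id)
  same <- gene_meta$chrom[ma] == gene_meta$chrom[mb]
  dist <- ifelse(same, abs(gene_meta$tss[ma] - gene_meta$tss[mb]),
                 NA_real_)
  data.frame(gene_a = ga, gene_b = gb,
             r = cor_mat[idx],
             same_chromosome = same, distance_bp = dist,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intra/inter-chromosomal connection statistics for two gene classes
#'
#' Counts intra- and inter-chromosomal connections per class, tests the
#' 2x2 contingency (Yates chi-square), and compares the
#' intra-chromosomal distance distributions by the rank-sum test.
#'
#' @param conn_a,conn_b Connection tables from [extract_connections()]
#'   for the two classes.
#' @return List with per-class `counts` (intra, inter, pct_inter,
#'   pct_intra, median_intra_distance), `chisq` and `distance_test`
#'   (`NA` when a class is empty).
#' @export
connection_stats <- function(conn_a, conn_b) {
  summarize <- function(cn) {
    intra <- sum(cn$same_chromosome)
    inter <- sum(!cn$same_chromosome)
    tot <- intra + inter
    list(intra = intra, inter = inter,
         pct_inter = if (tot > 0) 100 * inter / tot else NA_real_,
         pct_intra = if (tot > 0) 100 * intra / tot else NA_real_,
         median_intra_distance =
           if (intra > 0) stats::median(cn$distance_bp[cn$same_chromosome])
           else NA_real_)
  }
  sa <- summarize(conn_a); sb <- summarize(conn_b)
  chisq <- NULL; dist_test <- NULL
  if (nrow(conn_a) > 0 && nrow(conn_b) > 0) {
    tab <- matrix(c(sa$intra, sb$intra, sa$inter, sb$inter), 2, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      chisq <- chi_square_2x2(tab, yates = TRUE)
    }
    da <- conn_a$distance_bp[conn_a$same_chromosome]
    db <- conn_b$distance_bp[conn_b$same_chromosome]
    if (length(da) > 0 && length(db) > 0) {
      dist_test <- rank_sum_test(da, db, mode = "normal")
    }
  }
  list(class_a = sa, class_b = sb, chisq = chisq,
       distance_test = dist_test)
}
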