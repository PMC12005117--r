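test_that("the correlation read filter applies inclusive thresholds", {
  counts <- matrix(0, 3, 10,
                   dimnames = list(paste0("g", 1:3), paste0("c", 1:10)))
  counts[1, 1:5] <- 5        # 5 reads in exactly 5 cells -> kept
  counts[2, 1:4] <- 5        # only 4 cells -> dropped
  kept <- filter_correlation_genes(counts, paste0("c", 1:10))
  expect_equal(kept, "g1")
})

test_that("correlation matrices behave on exact and null data", {
  set.seed(61)
  layer <- rbind(x = rnorm(100))
  layer <- rbind(layer, y = -layer["x", ], z = rnorm(100))
  colnames(layer) <- paste0("c", 1:100)
  cm <- correlation_matrix(layer, c("x", "y", "z"), colnames(layer))
  expect_equal(cm["x", "x"], 1)
  expect_equal(cm["x", "y"], -1)
  expect_lt(abs(cm["x", "z"]), 0.3)
  expect_warning(
    correlation_matrix(rbind(layer, const = rep(1, 100)),
                       c("x", "const"), colnames(layer)),
    "constant")
  expect_error(correlation_matrix(layer, "x", paste0("c", 1:2)),
               "three cells")
})

test_that("affinity propagation recovers planted group structure", {
  s <- matrix(-5, 6, 6,
              dimnames = list(paste0("p", 1:6), paste0("p", 1:6)))
  s[1:3, 1:3] <- -0.1; s[4:6, 4:6] <- -0.1
  ap <- affinity_propagation(s)
  expect_equal(length(ap$clusters), 2)
  expect_setequal(ap$clusters[[1]], paste0("p", 1:3))
  # exemplars are their own exemplars
  ex <- unique(ap$exemplar)
  expect_true(all(ap$exemplar[ex] == ex))
  # single point
  ap1 <- affinity_propagation(matrix(0, 1, 1, dimnames = list("a", "a")))
  expect_equal(length(ap1$clusters), 1)
  expect_equal(unname(ap1$exemplar), "a")
})

test_that("preference extremes give singleton and single-cluster limits", {
  set.seed(62)
  s <- matrix(runif(25, -1, 0), 5, 5); s <- (s + t(s)) / 2
  expect_equal(length(affinity_propagation(s, preference = 10)$clusters),
               5)
  expect_equal(
    length(affinity_propagation(s, preference = -100)$clusters), 1)
})

test_that("affinity propagation attains the exhaustive optimum on small instances", {
  set.seed(63)
  hits <- 0
  for (i in 1:100) {
    n <- sample(3:8, 1)
    s <- matrix(runif(n * n, -1, 1), n, n); s <- (s + t(s)) / 2
    ap <- affinity_propagation(s)
    opt <- exhaustive_exemplar_search(s)
    if (ap$net_similarity >= opt$net_similarity - 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("connections are strict-threshold unique unordered pairs", {
  cm <- diag(3)
  dimnames(cm) <- list(paste0("g", 1:3), paste0("g", 1:3))
  cm["g1", "g2"] <- cm["g2", "g1"] <- 0.7
  cm["g1", "g3"] <- cm["g3", "g1"] <- 0.6   # exactly at threshold
  gm <- data.frame(gene_id = paste0("g", 1:3),
                   chrom = c("chr1", "chr1", "chr2"),
                   tss = c(100L, 20500L, 5000L))
  cn <- extract_connections(cm, gm)
  expect_equal(nrow(cn), 1)
  expect_equal(cn$gene_a, "g1")
  expect_true(cn$same_chromosome)
  expect_equal(cn$distance_bp, 20400)
  expect_error(extract_connections(cm, gm[1:2, ]), "annotation")
})

test_that("connection statistics reproduce counts, percentages and tests", {
  mk <- function(n_intra, n_inter, d) {
    data.frame(gene_a = "a", gene_b = "b", r = 0.9,
               same_chromosome = rep(c(TRUE, FALSE),
                                     c(n_intra, n_inter)),
               distance_bp = c(d, rep(NA, n_inter)))
  }
  st <- connection_stats(mk(3, 1, c(10e3, 20e3, 30e3)),
                         mk(1, 9, 5e3))
  expect_equal(st$class_a$pct_inter, 25)
  expect_equal(st$class_a$median_intra_distance, 20e3)
  expect_equal(st$class_b$pct_inter, 90)
  expect_s3_class(st$chisq, "test_result")
  # identical classes: no association
  same <- connection_stats(mk(5, 5, rep(1e3, 5)), mk(5, 5, rep(1e3, 5)))
  expect_equal(same$chisq$p, 1)
})

test_that("synthetic driven and enhanced genes reproduce the positional asymmetry", {
  exp <- default_exp()
  g <- exp$genes
  layer <- exp$layers$lognorm
  driven_cells <- c(cells_of(exp, "aire"), cells_of(exp, "aireless"))
  mim_cells <- cells_of(exp, c("m1", "m2", "m3"))
  driven <- intersect(
    g$gene_id[g$truth_class == "aire_driven"],
    filter_correlation_genes(exp$counts, driven_cells))
  enhanced <- intersect(
    g$gene_id[g$truth_class == "aire_enhanced"],
    filter_correlation_genes(exp$counts, mim_cells))
  cd <- extract_connections(correlation_matrix(layer, driven,
                                               driven_cells), g)
  ce <- extract_connections(correlation_matrix(layer, enhanced,
                                               mim_cells), g)
  # gate-shared adjacent pairs dominate the driven connections
  expect_gt(mean(cd$same_chromosome), 0.8)
  # driven pairs sit close together on the chromosome
  expect_lt(median(cd$distance_bp[cd$same_chromosome]), 60e3)
  # scattered module genes connect mostly across chromosomes
  expect_gt(mean(!ce$same_chromosome), 0.6)
  st <- connection_stats(cd, ce)
  expect_lt(st$chisq$p, 1e-6)
})

test_that("affinity propagation groups module genes into micro-clusters", {
  exp <- default_exp()
  g <- exp$genes
  mim_cells <- cells_of(exp, c("m1", "m2", "m3"))
  # one module per home cluster keeps the planted blocks separable
  mods <- c(1, 2, 3)
  genes <- g$gene_id[!is.na(g$module_id) & g$module_id %in% mods]
  cm <- correlation_matrix(exp$layers$lognorm, genes, mim_cells)
  ap <- affinity_propagation(cm)
  # genes of one module overwhelmingly share an exemplar
  co_frac <- vapply(mods, function(m) {
    members <- g$gene_id[!is.na(g$module_id) & g$module_id == m]
    max(table(ap$exemplar[members])) / length(members)
  }, numeric(1))
  expect_true(all(co_frac > 0.7))
  expect_gte(length(ap$clusters), 3)
})
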