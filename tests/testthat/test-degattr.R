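test_that("two-group DEG testing applies the expression-fraction filter", {
  set.seed(41)
  layer <- matrix(0, 3, 50,
                  dimnames = list(paste0("g", 1:3), paste0("c", 1:50)))
  a <- paste0("c", 1:25); b <- paste0("c", 26:50)
  layer[1, 1:25] <- rlnorm(25)         # on in A, off in B
  layer[2, c(1, 26)] <- c(2, 2)        # 1/25 = 4% in both -> excluded
  layer[3, ] <- rep(seq(0.1, 2, length.out = 25), 2)  # A == B exactly
  deg <- two_group_deg(layer, a, b)
  expect_false(deg$excluded[1])
  expect_lt(deg$p_adj[1], 1e-6)
  expect_gt(deg$log_fc[1], 0)
  expect_true(deg$excluded[2])
  expect_true(is.na(deg$p[2]))
  expect_gt(deg$p[3], 0.05)
  expect_equal(deg$log_fc[3], 0)
  expect_error(two_group_deg(layer, a, c(a[1], b)), "disjoint")
})

test_that("the log fold change follows the expm1-mean convention", {
  layer <- matrix(c(log(3), log(3), log(1), log(1)), 1, 4,
                  dimnames = list("g1", paste0("c", 1:4)))
  deg <- two_group_deg(layer, c("c1", "c2"), c("c3", "c4"),
                       min_frac = 0)
  expect_equal(deg$log_fc, log((2 + 1) / (0 + 1)))
})

test_that("Aire-DEG extraction keeps only significant up-regulation", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log_fc = c(0.8, -0.8, 0.5, 0.7),
                    p = c(1e-9, 1e-9, 0.5, 1e-9),
                    p_adj = c(0.001, 0.001, 1, 0.2),
                    excluded = c(FALSE, FALSE, FALSE, FALSE))
  expect_equal(extract_aire_degs(tab), "a")
})

test_that("the four attribution branches fire per the rule", {
  mk <- function(m) matrix(m, 1, 4,
                           dimnames = list("g", paste0("cl", 1:4)))
  # z-scores for means: standardized across clusters (sample sd)
  # exclusive: significant only in the top cluster
  p_excl <- mk(c(1e-9, 1, 1, 1))
  a1 <- attribute_genes(mk(c(5, 1, 0.5, 0.2)), p_excl)
  expect_equal(a1$branch, "exclusive")
  expect_equal(a1$assigned, "cl1")
  # zgap: two clusters significant but a clear z gap
  a2 <- attribute_genes(mk(c(5, 1.2, 0.6, 0.2)),
                        mk(c(1e-9, 1e-9, 1, 1)))
  expect_equal(a2$branch, "zgap")
  expect_equal(a2$assigned, "cl1")
  # multi_soft: nothing significant, assign positive-z clusters
  m3 <- mk(c(1.4, 0.7, 1.5, 0.8))
  a3 <- attribute_genes(m3, mk(c(1, 1, 1, 1)))
  expect_equal(a3$branch, "multi_soft")
  z3 <- (m3[1, ] - mean(m3[1, ])) / sd(m3[1, ])
  expect_equal(assigned_clusters(a3$assigned), names(z3)[z3 > 0])
  # multi_sig: several significant clusters without a sufficient gap
  a4 <- attribute_genes(mk(c(3, 2.8, 2.9, 0.1)),
                        mk(c(1e-9, 1e-9, 1, 1)))
  expect_equal(a4$branch, "multi_sig")
  expect_setequal(assigned_clusters(a4$assigned),
                  c("cl1", "cl2", "cl3"))
  expect_error(attribute_genes(matrix(1, 1, 1), matrix(1, 1, 1)),
               "two clusters")
})

test_that("attribution branches are mutually exclusive and exhaustive", {
  set.seed(42)
  means <- matrix(rexp(300), 60, 5,
                  dimnames = list(paste0("g", 1:60), paste0("cl", 1:5)))
  p_adj <- matrix(sample(c(1e-8, 0.5), 300, replace = TRUE), 60, 5,
                  dimnames = dimnames(means))
  at <- attribute_genes(means, p_adj)
  expect_true(all(at$branch %in%
                    c("exclusive", "zgap", "multi_soft", "multi_sig")))
  expect_true(all(nchar(at$assigned) > 0))
})

test_that("Aire-DEG classes follow the attribution", {
  at <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   top_cluster = c("aire", "m1", "aire", "m2"),
                   branch = "exclusive",
                   assigned = c("aire", "m1", "aire", "aire,m2"),
                   stringsAsFactors = FALSE)
  cl <- classify_aire_degs(at, c("g1", "g2", "g4"), "aire")
  expect_equal(cl$class, c("aire_driven", "aire_enhanced", "none",
                           "aire_enhanced"))
})

test_that("maturation dynamics compare endpoint cluster means", {
  layer <- matrix(c(1, 1, 2, 2, 3, 3,
                    3, 3, 2, 2, 1, 1,
                    1, 1, 5, 5, 1, 1), 3, 6, byrow = TRUE,
                  dimnames = list(c("up", "down", "tie"),
                                  paste0("c", 1:6)))
  cl <- rep(c("low", "mid", "aire"), each = 2)
  dyn <- classify_dynamics(layer, cl, c("low", "mid", "aire"))
  expect_equal(dyn$dynamics, c("mtec_high_up", "mtec_high_down",
                               "mtec_high_down"))
  expect_equal(dyn$tie, c(FALSE, FALSE, TRUE))
  expect_error(classify_dynamics(layer, cl, c("low", "absent")),
               "empty")
})

test_that("Aire-neutral calling combines bulk and single-cell criteria", {
  sc <- data.frame(gene = c("a", "b", "c", "d"),
                   log_fc = 0, p = 1,
                   p_adj = c(0.5, 0.5, 0.5, 1e-7),
                   excluded = FALSE)
  bulk <- data.frame(gene = c("a", "b", "c", "d"),
                     log2_fc = c(0.1, 0.5, 0.1, 0.1),
                     fdr = c(0.3, 0.3, 0.01, 0.3))
  expect_equal(call_aire_neutral(sc, bulk), "a")
})

test_that("the classification pipeline recovers the simulated truth", {
  exp <- small_exp()
  layer <- exp$layers$lognorm
  deg <- two_group_deg(layer, cells_of(exp, "aire", "WT"),
                       cells_of(exp, "aireless"))
  degs <- extract_aire_degs(deg)
  g <- exp$genes
  induced <- g$gene_id[g$truth_class %in% c("aire_driven",
                                            "aire_enhanced")]
  expect_gt(mean(induced %in% degs), 0.85)
  # at the default cohort size nearly all induced genes are recovered
  dexp <- default_exp()
  ddeg <- two_group_deg(dexp$layers$lognorm,
                        cells_of(dexp, "aire", "WT"),
                        cells_of(dexp, "aireless"))
  ddegs <- extract_aire_degs(ddeg)
  dinduced <- dexp$genes$gene_id[
    dexp$genes$truth_class %in% c("aire_driven", "aire_enhanced")]
  expect_gt(mean(dinduced %in% ddegs), 0.9)
  high_wt <- exp$cells$genotype == "WT" &
    exp$cells$cluster %in% c("aire", "ta", "m1", "m2", "m3")
  ms <- cluster_marker_stats(layer[, high_wt, drop = FALSE],
                             exp$cells$cluster[high_wt])
  at <- attribute_genes(ms$means, ms$p_adj, ms$delta)
  cl <- classify_aire_degs(at, degs, "aire")
  called_driven <- cl$gene[cl$class == "aire_driven"]
  truth_driven <- g$gene_id[g$truth_class == "aire_driven"]
  expect_gt(mean(called_driven %in% truth_driven), 0.8)
  expect_gt(mean(truth_driven %in% called_driven), 0.85)
  # driven genes rise along the maturation path
  dyn <- classify_dynamics(layer, exp$cells$cluster,
                           c("low", "ta", "aire"))
  up <- dyn$gene[dyn$dynamics == "mtec_high_up"]
  expect_gt(mean(truth_driven %in% up), 0.95)
})

test_that("permuting genotype labels destroys the Aire-DEG set", {
  exp <- small_exp()
  layer <- exp$layers$lognorm
  set.seed(43)
  aire_wt <- cells_of(exp, "aire", "WT")
  ko <- cells_of(exp, "aireless")
  pool <- c(aire_wt, ko)
  n_deg <- replicate(5, {
    perm <- sample(pool)
    a <- perm[seq_along(aire_wt)]
    b <- perm[-seq_along(aire_wt)]
    length(extract_aire_degs(two_group_deg(layer, a, b)))
  })
  expect_lt(mean(n_deg) / nrow(layer), 0.05)
})
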