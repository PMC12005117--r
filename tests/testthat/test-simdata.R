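test_that("genome placement respects pairs and is reproducible", {
  cs <- default_chrom_sizes()
  g0 <- build_genome(100, cs, adjacency_fraction = 0, seed = 31)
  expect_equal(nrow(g0), 100)
  expect_true(all(is.na(g0$pair_id)))
  expect_true(all(g0$tss >= 0 & g0$tss < cs[g0$chrom]))
  expect_true(all(g0$length_bp > 0))
  expect_false(anyDuplicated(g0$gene_id) > 0)

  g1 <- build_genome(200, cs, adjacency_fraction = 0.1, seed = 32)
  pd <- tapply(g1$tss, g1$pair_id, function(t) abs(diff(t)))
  expect_equal(length(pd), 10)
  expect_gt(median(pd), 10e3)
  expect_lt(median(pd), 40e3)
  same_chr <- tapply(g1$chrom, g1$pair_id,
                     function(ch) length(unique(ch)) == 1)
  expect_true(all(same_chr))

  g2 <- build_genome(200, cs, adjacency_fraction = 0.1, seed = 32)
  expect_identical(g1, g2)
  expect_error(build_genome(100, c(chrA = 500), seed = 1), "too small")
})

test_that("the design table matches the requested cluster sizes", {
  d <- small_design()
  cm <- build_design(d)
  expect_equal(nrow(cm), sum(d$n_cells))
  expect_equal(sum(cm$cluster == "aire" & cm$genotype != "WT"), 0)
  expect_equal(sum(cm$cluster == "aire"),
               d$n_cells[d$cluster == "aire"])
  cm2 <- build_design(d)
  expect_identical(cm$cell_id, cm2$cell_id)
  d_bad <- d; d_bad$n_cells[1] <- -5
  expect_error(build_design(d_bad), "negative")
  d_ko <- d; d_ko$genotype[d_ko$cluster == "aire"] <- "Aire-KO"
  expect_error(build_design(d_ko), "WT")
})

test_that("simulated counts carry the designed stochastic structure", {
  exp <- small_exp()
  g <- exp$genes
  aire_wt <- exp$cells$cluster == "aire" & exp$cells$genotype == "WT"
  driven <- which(g$truth_class == "aire_driven" & is.na(g$pair_id))
  # empirical firing fraction of unpaired driven genes ~ p_express
  frac <- rowMeans(exp$counts[driven, aire_wt, drop = FALSE] > 0)
  p <- small_params()$p_express
  n <- sum(aire_wt)
  se <- sqrt(p * (1 - p) / n)
  # gene-level fractions include baseline leakage; the mean over genes
  # must sit near p_express within 3 SE of the grand binomial
  expect_lt(abs(mean(frac) - p), 3 * se + 0.02)
  # driven genes near-silent in the KO counterpart
  ko <- exp$cells$cluster == "aireless"
  expect_lt(mean(exp$counts[driven, ko] > 0), 0.05)
  expect_error(
    simulate_counts(g[, setdiff(names(g), "truth_class")],
                    exp$cells, small_params()),
    "truth classes")
})

test_that("neutral genes have exchangeable count distributions across genotypes", {
  # two-sample rank test on raw counts approximately uniform over genes
  exp <- small_exp()
  g <- exp$genes
  a <- match(cells_of(exp, "aire", "WT"), colnames(exp$counts))
  b <- match(cells_of(exp, "aireless"), colnames(exp$counts))
  neutral <- g$gene_id[g$truth_class == "aire_neutral"]
  rows <- match(neutral, rownames(exp$counts))
  ps <- vapply(rows, function(i) {
    rank_sum_test(exp$counts[i, a], exp$counts[i, b],
                  mode = "normal")$p
  }, numeric(1))
  expect_gt(mean(ps > 0.01), 0.95)
  expect_gt(mean(ps > 0.5), 0.3)   # not all piled near 0 or 1
})

test_that("module genes co-express within modules but not across", {
  exp <- default_exp()
  g <- exp$genes
  m1cells <- cells_of(exp, "m1")
  mods <- sort(unique(g$module_id[!is.na(g$module_id) &
                                    g$module_cluster == "m1"]))
  expect_gte(length(mods), 2)
  ga <- g$gene_id[!is.na(g$module_id) & g$module_id == mods[1]]
  gb <- g$gene_id[!is.na(g$module_id) & g$module_id == mods[2]]
  cm <- correlation_matrix(exp$layers$lognorm, c(ga, gb), m1cells)
  within_r <- cm[ga, ga][upper.tri(diag(length(ga)))]
  across_r <- cm[ga, gb]
  expect_gt(mean(within_r), 0.6)
  expect_lt(abs(mean(across_r)), 0.2)
})

test_that("the same seed reproduces the whole dataset bit-identically", {
  e1 <- simulate_tec_dataset(small_params(77), design = small_design())
  e2 <- simulate_tec_dataset(small_params(77), design = small_design())
  expect_identical(e1$counts, e2$counts)
  expect_identical(e1$genes, e2$genes)
})

test_that("spike-in libraries record a recoverable truth", {
  sl <- simulate_spike_library(20, depth_range = c(1e6, 1e6), seed = 33)
  expect_equal(nrow(sl), 20)
  expect_identical(sl, simulate_spike_library(20,
                                              depth_range = c(1e6, 1e6),
                                              seed = 33))
  fr <- compute_frspike(sl$rqc_target, sl$rqc_spike)
  se <- sqrt(sl$true_frspike * (1 - sl$true_frspike) / sl$rqc_total)
  expect_true(all(abs(fr - sl$true_frspike) < 3 * se + 1e-3))
  expect_error(simulate_spike_library(3, frspike_range = c(0, 1.2)))
})

test_that("simulated peaks and tracks have known geometry", {
  g <- build_genome(20, default_chrom_sizes(), seed = 34)
  tp <- simulate_tracks_peaks(g, default_chrom_sizes(),
                              peak_genes = g$gene_id[1:5],
                              peak_offset = 0, peak_width = 400,
                              hi_genes = g$gene_id[1],
                              bg_value = 2, hi_value = 2)
  prox <- peak_proximity(tp$peaks,
                         data.frame(gene_id = g$gene_id[1:5],
                                    chrom = g$chrom[1:5],
                                    tss = g$tss[1:5]))
  expect_equal(prox$nearest_distance, rep(0, 5))
  # uniform track value v -> locus density v everywhere
  loci <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                     start = g$tss, end = g$tss + g$length_bp)
  dens <- locus_density(tp$track, loci)
  inb <- loci$start > 2e4 & loci$end < 5e7 - 2e4
  expect_equal(unname(dens[inb]), rep(2, sum(inb)))
  tp2 <- simulate_tracks_peaks(g, default_chrom_sizes(),
                               peak_genes = g$gene_id[1:5],
                               peak_offset = 0, peak_width = 400,
                               hi_genes = g$gene_id[1],
                               bg_value = 2, hi_value = 2)
  expect_identical(tp, tp2)
})
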