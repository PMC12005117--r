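# Synthetic data generator. Emulates the statistical structure the
# downstream analyses assume: a WT-only Aire-expressing cluster whose
# target genes fire stochastically in a small fraction of cells,
# mimetic-cell clusters expressing latent co-expression modules in all
# genotypes, cluster marker genes, gene genomic positions with designated
# adjacent pairs, and dual-genome spike-in sequencing libraries. Ground
# truth is recorded on the gene table; no analysis function reads it.

#' Simulation parameters
#'
#' Bundles the generative settings with the defaults that define the
#' package's reference study conditions: Aire-driven genes fire in an
#' Aire-expressing cell with probability `p_express = 0.131`, a tenth of
#' them sit in adjacent intra-chromosomal pairs with a median TSS
#' separation of 20.4 kb, and Aire-enhanced genes load on per-cell
#' gamma-distributed module activities within mimetic clusters.
#'
#' @param n_driven,n_enhanced,n_neutral Genes per truth class.
#' @param n_markers_per_cluster Constitutive marker genes per cluster.
#' @param p_express Bernoulli firing probability of an induced gene in an
#'   Aire-expressing (WT) cell.
#' @param pair_fraction Fraction of Aire-driven genes placed as adjacent
#'   intra-chromosomal pairs sharing one expression gate.
#' @param pair_distance_median Median TSS-to-TSS separation (bp) of the
#'   designated pairs.
#' @param n_modules Number of latent co-expression modules carrying the
#'   Aire-enhanced genes.
#' @param induced_mu Negative-binomial mean of an induced (fired or
#'   module-active, activity 1) gene.
#' @param marker_mu Negative-binomial mean of a marker gene in its home
#'   cluster.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expression mean.
#' @param driven_baseline_mu,enhanced_baseline_mu Baseline negative
#'   binomial mean of induced genes outside their induced context.
#' @param module_shape Shape of the gamma-distributed (mean 1) per-cell
#'   module activity; smaller values give burstier, more correlated
#'   modules.
#' @param dispersion Negative-binomial size parameter (all genes).
#' @param size_factor_sdlog Log-normal sd of per-cell size factors.
#' @param seed Master seed recorded in output metadata.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_driven = 500, n_enhanced = 500, n_neutral = 500,
                       n_markers_per_cluster = 20,
                       p_express = 0.131,
                       pair_fraction = 0.1,
                       pair_distance_median = 20400,
                       n_modules = 10,
                       induced_mu = 20,
                       marker_mu = 10,
                       baseline_meanlog = log(0.2),
                       baseline_sdlog = 1,
                       driven_baseline_mu = 0.01,
                       enhanced_baseline_mu = 0.05,
                       module_shape = 1.5,
                       dispersion = 5,
                       size_factor_sdlog = 0.3,
                       seed = 1L) {
  stopifnot(p_express >= 0, p_express <= 1,
            pair_fraction >= 0, pair_fraction <= 1)
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

#' Default chromosome sizes of the synthetic genome
#'
#' Five chromosomes of 50 Mb each; small enough for fast placement,
#' large enough that uniformly placed gene pairs land on the same
#' chromosome only rarely.
#' @return Named integer vector of chromosome lengths in bp.
#' @export
default_chrom_sizes <- function() {
  stats::setNames(rep(5e7, 5), paste0("chr", 1:5))
}

#' Default cell-cluster design
#'
#' The reference design of the simulated cohort: an mTEC-low cluster
#' (`low`), a transit-amplifying cluster (`ta`), a WT-only
#' Aire-expressing cluster (`aire`, 500 WT cells), its KO-only
#' counterpart (`aireless`), and three mimetic clusters (`m1`-`m3`)
#' present in both genotypes.
#' @return Data frame with columns `cluster`, `genotype`, `n_cells`.
#' @export
default_design <- function() {
  data.frame(
    cluster = c("low", "low", "ta", "ta", "aire", "aireless",
                "m1", "m1", "m2", "m2", "m3", "m3"),
    genotype = c("WT", "Aire-KO", "WT", "Aire-KO", "WT", "Aire-KO",
                 "WT", "Aire-KO", "WT", "Aire-KO", "WT", "Aire-KO"),
    n_cells = c(300, 300, 200, 200, 500, 500,
                150, 150, 150, 150, 150, 150),
    stringsAsFactors = FALSE
  )
}

#' Place genes on a synthetic genome
#'
#' Genes are assigned to chromosomes with probability proportional to
#' chromosome size and placed uniformly, except for designated adjacent
#' pairs whose TSS separation is drawn log-normally with the requested
#' median. Pairs are recorded in the `pair_id` column.
#'
#' @param n_genes Number of genes.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param adjacency_fraction Fraction of genes placed as members of
#'   adjacent pairs (must be in `[0, 1]`).
#' @param pair_distance_median Median TSS separation of pairs, bp.
#' @param pair_distance_sdlog Log-normal sd of pair separations.
#' @param seed Random seed.
#' @return Gene table: `gene_id`, `chrom`, `tss` (0-based), `strand`,
#'   `length_bp`, `pair_id` (NA for unpaired genes).
#' @export
build_genome <- function(n_genes, chrom_sizes, adjacency_fraction = 0,
                         pair_distance_median = 20400,
                         pair_distance_sdlog = 0.4, seed = 1L) {
  if (length(chrom_sizes) == 0L) stop("chrom_sizes must be non-empty")
  if (is.null(names(chrom_sizes))) stop("chrom_sizes must be named")
  if (adjacency_fraction < 0 || adjacency_fraction > 1) {
    stop("adjacency_fraction must lie in [0, 1]")
  }
  set.seed(seed)
  n_pairs <- floor(n_genes * adjacency_fraction / 2)
  n_single <- n_genes - 2L * n_pairs
  probs <- chrom_sizes / sum(chrom_sizes)
  chrom_single <- sample(names(chrom_sizes), n_single + n_pairs,
                         replace = TRUE, prob = probs)
  tallies <- table(factor(chrom_single, levels = names(chrom_sizes)))
  if (any(chrom_sizes < as.numeric(tallies) * 100)) {
    stop("chromosome too small to host the requested genes")
  }
  # anchors: singles plus one anchor per pair
  anchor_tss <- floor(stats::runif(n_single + n_pairs) *
                        (chrom_sizes[chrom_single] - 1))
  genes <- data.frame(
    chrom = chrom_single,
    tss = as.integer(anchor_tss),
    pair_id = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (n_pairs > 0) {
    anchor_rows <- n_single + seq_len(n_pairs)
    genes$pair_id[anchor_rows] <- seq_len(n_pairs)
    d <- stats::rlnorm(n_pairs, meanlog = log(pair_distance_median),
                       sdlog = pair_distance_sdlog)
    partner_tss <- genes$tss[anchor_rows] + round(d)
    lim <- chrom_sizes[genes$chrom[anchor_rows]] - 1
    flip <- partner_tss > lim
    partner_tss[flip] <- genes$tss[anchor_rows][flip] - round(d)[flip]
    partner_tss <- pmax(0, pmin(partner_tss, lim))
    partners <- data.frame(
      chrom = genes$chrom[anchor_rows],
      tss = as.integer(partner_tss),
      pair_id = seq_len(n_pairs),
      stringsAsFactors = FALSE
    )
    genes <- rbind(genes, partners)
  }
  # shuffle so class assignment downstream is not positional
  genes <- genes[sample(nrow(genes)), , drop = FALSE]
  genes$gene_id <- sprintf("g%04d", seq_len(n_genes))
  genes$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes$length_bp <- pmax(200L, as.integer(round(
    stats::rlnorm(n_genes, meanlog = log(2000), sdlog = 0.6))))
  rownames(genes) <- genes$gene_id
  genes[, c("gene_id", "chrom", "tss", "strand", "length_bp", "pair_id")]
}

#' Build the per-cell design table
#'
#' @param cluster_sizes Data frame with columns `cluster`, `genotype`,
#'   `n_cells`.
#' @param aire_cluster Name of the WT-only Aire-expressing cluster.
#' @param ko_counterpart Name of its KO-only counterpart cluster.
#' @param age_group Age label applied to all cells.
#' @param seed Kept for interface symmetry; the design is deterministic.
#' @return Cell table: `cell_id`, `cluster`, `genotype`, `sample`,
#'   `age_group`.
#' @export
build_design <- function(cluster_sizes, aire_cluster = "aire",
                         ko_counterpart = "aireless",
                         age_group = "adult", seed = 1L) {
  req <- c("cluster", "genotype", "n_cells")
  if (!all(req %in% names(cluster_sizes))) {
    stop("cluster_sizes needs columns cluster, genotype, n_cells")
  }
  if (any(cluster_sizes$n_cells < 0)) stop("negative cluster sizes")
  aire_rows <- cluster_sizes$cluster == aire_cluster
  if (!any(aire_rows & cluster_sizes$genotype == "WT" &
             cluster_sizes$n_cells > 0)) {
    stop("design must declare a WT Aire-expressing cluster")
  }
  if (any(aire_rows & cluster_sizes$genotype != "WT" &
            cluster_sizes$n_cells > 0)) {
    stop("the Aire-expressing cluster must contain WT cells only")
  }
  if (!ko_counterpart %in% cluster_sizes$cluster) {
    stop("design must declare the KO counterpart cluster")
  }
  idx <- rep(seq_len(nrow(cluster_sizes)), cluster_sizes$n_cells)
  cells <- data.frame(
    cluster = cluster_sizes$cluster[idx],
    genotype = cluster_sizes$genotype[idx],
    stringsAsFactors = FALSE
  )
  cells$cell_id <- sprintf("cell_%05d", seq_len(nrow(cells)))
  cells$sample <- paste(cells$genotype, age_group, sep = "_")
  cells$age_group <- age_group
  rownames(cells) <- cells$cell_id
  attr(cells, "aire_cluster") <- aire_cluster
  attr(cells, "ko_counterpart") <- ko_counterpart
  cells[, c("cell_id", "cluster", "genotype", "sample", "age_group")]
}

#' Assign ground-truth classes to genes
#'
#' Aire-driven genes absorb all designated adjacent pairs first (paired
#' genes share one expression gate, reproducing intra-chromosomal
#' co-expression); Aire-enhanced genes are split across the latent
#' modules, each homed in one mimetic cluster; marker genes are assigned
#' per cluster; the remainder is Aire-neutral.
#'
#' @param gene_meta Gene table from [build_genome()].
#' @param params A [sim_params()] object.
#' @param clusters Character vector of all cluster names (markers are
#'   generated for each).
#' @param mimetic_clusters Clusters hosting the enhanced-gene modules.
#' @return `gene_meta` with columns `truth_class`, `module_id`,
#'   `module_cluster`, `marker_cluster` added.
#' @export
assign_truth_classes <- function(gene_meta, params, clusters,
                                 mimetic_clusters) {
  n_mark <- params$n_markers_per_cluster * length(clusters)
  need <- params$n_driven + params$n_enhanced + params$n_neutral + n_mark
  if (nrow(gene_meta) != need) {
    stop(sprintf("gene_meta has %d genes but the class design needs %d",
                 nrow(gene_meta), need))
  }
  g <- gene_meta
  g$truth_class <- NA_character_
  g$module_id <- NA_integer_
  g$module_cluster <- NA_character_
  g$marker_cluster <- NA_character_
  paired <- which(!is.na(g$pair_id))
  if (length(paired) > params$n_driven) {
    stop("more paired genes than Aire-driven slots")
  }
  free <- setdiff(seq_len(nrow(g)), paired)
  driven <- c(paired, free[seq_len(params$n_driven - length(paired))])
  free <- setdiff(free, driven)
  enhanced <- free[seq_len(params$n_enhanced)]
  free <- setdiff(free, enhanced)
  neutral <- free[seq_len(params$n_neutral)]
  markers <- setdiff(free, neutral)
  g$truth_class[driven] <- "aire_driven"
  g$truth_class[enhanced] <- "aire_enhanced"
  g$truth_class[neutral] <- "aire_neutral"
  g$truth_class[markers] <- "mimetic_marker"
  g$module_id[enhanced] <- rep_len(seq_len(params$n_modules),
                                   length(enhanced))
  module_home <- rep_len(mimetic_clusters, params$n_modules)
  g$module_cluster[enhanced] <- module_home[g$module_id[enhanced]]
  g$marker_cluster[markers] <- rep_len(clusters, length(markers))
  g
}

#' Simulate a gene-by-cell count matrix
#'
#' Negative-binomial counts with log-normal per-cell size factors.
#' Aire-driven genes draw from the induced mean only in Aire-cluster WT
#' cells passing an independent Bernoulli(`p_express`) gate (designated
#' adjacent pairs share one gate); Aire-enhanced genes scale with a
#' per-cell gamma module activity in their home mimetic cluster in all
#' genotypes, plus the stochastic gate in the WT Aire cluster; marker
#' genes are constitutively elevated in their home cluster; Aire-neutral
#' genes have one distribution everywhere.
#'
#' @param gene_meta Gene table with truth classes
#'   (see [assign_truth_classes()]).
#' @param cell_meta Cell table from [build_design()].
#' @param params A [sim_params()] object.
#' @return A [tec_experiment] with the raw `counts` matrix.
#' @export
simulate_counts <- function(gene_meta, cell_meta, params) {
  if (is.null(gene_meta$truth_class) || anyNA(gene_meta$truth_class)) {
    stop("truth classes must be assigned before simulating counts")
  }
  set.seed(params$seed)
  n_g <- nrow(gene_meta); n_c <- nrow(cell_meta)
  aire_cl <- attr(cell_meta, "aire_cluster") %||% "aire"
  cls <- gene_meta$truth_class

  base_mu <- stats::rlnorm(n_g, params$baseline_meanlog,
                           params$baseline_sdlog)
  base_mu[cls == "aire_driven"] <- params$driven_baseline_mu
  base_mu[cls == "aire_enhanced"] <- params$enhanced_baseline_mu
  base_mu[cls == "mimetic_marker"] <-
    stats::rlnorm(sum(cls == "mimetic_marker"), log(0.1), 1)

  mu <- matrix(base_mu, nrow = n_g, ncol = n_c)

  # markers: constitutive in home cluster, both genotypes
  for (i in which(cls == "mimetic_marker")) {
    mu[i, cell_meta$cluster == gene_meta$marker_cluster[i]] <-
      params$marker_mu
  }

  # enhanced: module activity in home mimetic cluster, all genotypes
  for (m in seq_len(params$n_modules)) {
    gene_rows <- which(!is.na(gene_meta$module_id) &
                         gene_meta$module_id == m)
    if (length(gene_rows) == 0) next
    home <- gene_meta$module_cluster[gene_rows[1]]
    cell_cols <- which(cell_meta$cluster == home)
    act <- stats::rgamma(length(cell_cols), shape = params$module_shape,
                         rate = params$module_shape)
    mu[gene_rows, cell_cols] <-
      params$induced_mu * rep(act, each = length(gene_rows))
  }

  # stochastic gates in Aire-cluster WT cells
  aire_cells <- which(cell_meta$cluster == aire_cl &
                        cell_meta$genotype == "WT")
  if (length(aire_cells) > 0) {
    driven_rows <- which(cls == "aire_driven")
    gate_group <- ifelse(is.na(gene_meta$pair_id[driven_rows]),
                         gene_meta$gene_id[driven_rows],
                         paste0("pair_", gene_meta$pair_id[driven_rows]))
    groups <- unique(gate_group)
    gates <- matrix(stats::rbinom(length(groups) * length(aire_cells), 1,
                                  params$p_express),
                    nrow = length(groups),
                    dimnames = list(groups, NULL))
    fired <- gates[match(gate_group, groups), , drop = FALSE] == 1
    sub <- mu[driven_rows, aire_cells, drop = FALSE]
    sub[fired] <- params$induced_mu
    mu[driven_rows, aire_cells] <- sub

    enh_rows <- which(cls == "aire_enhanced")
    fired_e <- matrix(stats::rbinom(length(enh_rows) * length(aire_cells),
                                    1, params$p_express),
                      nrow = length(enh_rows)) == 1
    sub <- mu[enh_rows, aire_cells, drop = FALSE]
    sub[fired_e] <- params$induced_mu
    mu[enh_rows, aire_cells] <- sub
  }

  sf <- stats::rlnorm(n_c, 0, params$size_factor_sdlog)
  mu <- sweep(mu, 2, sf, `*`)
  counts <- matrix(stats::rnbinom(n_g * n_c, mu = mu,
                                  size = params$dispersion),
                   nrow = n_g,
                   dimnames = list(gene_meta$gene_id, cell_meta$cell_id))
  tec_experiment(counts, cell_meta, gene_meta,
                 meta = list(seed = params$seed))
}

#' Simulate the full synthetic cohort
#'
#' Wires [build_genome()], [build_design()], [assign_truth_classes()] and
#' [simulate_counts()] with the default design and attaches the
#' log-normalized layer.
#'
#' @param params A [sim_params()] object.
#' @param design Cluster design table, default [default_design()].
#' @param chrom_sizes Chromosome sizes, default [default_chrom_sizes()].
#' @return A [tec_experiment] with layers `lognorm`.
#' @export
simulate_tec_dataset <- function(params = sim_params(),
                                 design = default_design(),
                                 chrom_sizes = default_chrom_sizes()) {
  clusters <- unique(design$cluster)
  mimetic <- grep("^m", clusters, value = TRUE)
  if (length(mimetic) == 0) mimetic <- clusters
  n_mark <- params$n_markers_per_cluster * length(clusters)
  n_genes <- params$n_driven + params$n_enhanced + params$n_neutral +
    n_mark
  n_paired <- 2 * floor(params$n_driven * params$pair_fraction / 2)
  genome <- build_genome(
    n_genes, chrom_sizes,
    adjacency_fraction = n_paired / n_genes,
    pair_distance_median = params$pair_distance_median,
    seed = params$seed
  )
  genome <- assign_truth_classes(genome, params, clusters, mimetic)
  cells <- build_design(design, seed = params$seed)
  exp <- simulate_counts(genome, cells, params)
  exp$layers$lognorm <- lognormalize(exp$counts)
  exp
}

#' Simulate dual-genome spike-in sequencing libraries
#'
#' Per sample, a true spike-in cell fraction and assay efficiency are
#' drawn from the given ranges; reads are split between target and spike
#' genomes binomially so that the genome-size-normalized read fractions
#' recover the true spike fraction in expectation, and spike reads fall
#' in peaks with probability equal to the true efficiency.
#'
#' @param n_samples Number of libraries.
#' @param depth_range Total read-count range.
#' @param frspike_range Range of true spike-in cell fractions (in (0,1)).
#' @param eff_range Range of true assay efficiencies (in (0,1)).
#' @param genome_size_target,genome_size_spike Effective genome sizes of
#'   the target and spike species.
#' @param seed Random seed.
#' @return Data frame with per-sample read counts and the recorded truth
#'   (`true_frspike`, `true_eff`).
#' @export
simulate_spike_library <- function(n_samples,
                                   depth_range = c(5e5, 2e6),
                                   frspike_range = c(0.35, 0.55),
                                   eff_range = c(0.30, 0.43),
                                   genome_size_target = 2.49e9,
                                   genome_size_spike = 2.86e9,
                                   seed = 1L) {
  stopifnot(all(frspike_range > 0), all(frspike_range < 1),
            all(eff_range > 0), all(eff_range < 1))
  set.seed(seed)
  f <- stats::runif(n_samples, frspike_range[1], frspike_range[2])
  eff <- stats::runif(n_samples, eff_range[1], eff_range[2])
  depth <- round(stats::runif(n_samples, depth_range[1], depth_range[2]))
  # read-fraction q solving (q/Gs)/(q/Gs + (1-q)/Gt) = f
  odds <- f / (1 - f) * genome_size_spike / genome_size_target
  q <- odds / (1 + odds)
  spike <- stats::rbinom(n_samples, depth, q)
  target <- depth - spike
  rip_spike <- stats::rbinom(n_samples, spike, eff)
  data.frame(
    sample = sprintf("s%02d", seq_len(n_samples)),
    rqc_target = target, rqc_spike = spike, rqc_total = depth,
    rip_spike = rip_spike,
    true_frspike = f, true_eff = eff,
    stringsAsFactors = FALSE
  )
}

#' Simulate peak sets and piecewise-constant signal tracks
#'
#' Places one peak near the TSS of each selected gene at a controlled
#' offset, and builds a piecewise-constant coverage track with an
#' elevated value over the loci of selected genes on a uniform
#' background, so the mean signal over any interval is known exactly.
#'
#' @param gene_meta Gene table with `chrom` and `tss`.
#' @param chrom_sizes Named chromosome lengths.
#' @param peak_genes Gene ids receiving a peak (default: all).
#' @param peak_offset TSS-to-peak-midpoint offsets (recycled; bp,
#'   signed).
#' @param peak_width Peak width, bp.
#' @param hi_genes Gene ids whose +/-10 kb locus carries the elevated
#'   track value.
#' @param bg_value,hi_value Background and elevated track values.
#' @param seed Random seed (used only when `peak_offset` is NULL, in
#'   which case offsets are drawn normal with sd 5 kb).
#' @return List with `peaks` (BED-like data frame with `qvalue`) and
#'   `track` (`chrom`, `start`, `end`, `value`; 0-based half-open,
#'   non-overlapping).
#' @export
simulate_tracks_peaks <- function(gene_meta, chrom_sizes,
                                  peak_genes = gene_meta$gene_id,
                                  peak_offset = NULL, peak_width = 500,
                                  hi_genes = character(),
                                  bg_value = 1, hi_value = 4,
                                  seed = 1L) {
  set.seed(seed)
  rows <- match(peak_genes, gene_meta$gene_id)
  if (anyNA(rows)) stop("unknown gene ids in peak_genes")
  if (is.null(peak_offset)) {
    peak_offset <- round(stats::rnorm(length(rows), 0, 5000))
  }
  peak_offset <- rep_len(peak_offset, length(rows))
  mid <- gene_meta$tss[rows] + peak_offset
  start <- pmax(0, mid - peak_width %/% 2)
  peaks <- data.frame(
    chrom = gene_meta$chrom[rows],
    start = as.integer(start),
    end = as.integer(start + peak_width),
    name = paste0("peak_", seq_along(rows)),
    score = 0L, strand = ".",
    qvalue = 0.001,
    stringsAsFactors = FALSE
  )
  track <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    hi_rows <- which(gene_meta$gene_id %in% hi_genes &
                       gene_meta$chrom == ch)
    if (length(hi_rows) == 0) {
      return(data.frame(chrom = ch, start = 0L, end = as.integer(size),
                        value = bg_value))
    }
    win <- cbind(pmax(0, gene_meta$tss[hi_rows] - 10000),
                 pmin(size, gene_meta$tss[hi_rows] + 10000))
    win <- win[order(win[, 1]), , drop = FALSE]
    merged <- list(win[1, ])
    for (i in seq_len(nrow(win))[-1]) {
      last <- merged[[length(merged)]]
      if (win[i, 1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], win[i, 2]))
      } else merged[[length(merged) + 1]] <- win[i, ]
    }
    merged <- do.call(rbind, merged)
    segs <- data.frame(chrom = character(), start = integer(),
                       end = integer(), value = numeric())
    pos <- 0
    for (i in seq_len(nrow(merged))) {
      if (merged[i, 1] > pos) {
        segs <- rbind(segs, data.frame(chrom = ch, start = pos,
                                       end = merged[i, 1],
                                       value = bg_value))
      }
      segs <- rbind(segs, data.frame(chrom = ch, start = merged[i, 1],
                                     end = merged[i, 2],
                                     value = hi_value))
      pos <- merged[i, 2]
    }
    if (pos < size) {
      segs <- rbind(segs, data.frame(chrom = ch, start = pos,
                                     end = size, value = bg_value))
    }
    segs$start <- as.integer(segs$start); segs$end <- as.integer(segs$end)
    segs
  }))
  rownames(track) <- NULL
  list(peaks = peaks, track = track)
}

#' Simulate a TF motif-activity matrix
#'
#' For each named TF gene, the per-cell activity tracks the cluster-mean
#' expression of that gene (plus cell-level noise); additional null TFs
#' carry cluster-structured activity unrelated to any expression profile.
#' This mirrors a chromVAR-style deviation matrix as used for
#' expression-activity correlation analyses.
#'
#' @param layer Genes x cells log-normalized expression matrix.
#' @param clusters Cluster label per cell.
#' @param tf_genes Gene ids (rows of `layer`) acting as coupled TFs:
#'   their activity tracks their own expression.
#' @param null_tfs Gene ids receiving cluster-structured activity
#'   unrelated to their expression (calibration nulls).
#' @param noise_sd Cell-level noise sd.
#' @param seed Random seed.
#' @return TFs x cells activity matrix (rows `tf_genes` then
#'   `null_tfs`).
#' @export
simulate_tf_activity <- function(layer, clusters, tf_genes,
                                 null_tfs = character(),
                                 noise_sd = 0.3, seed = 1L) {
  set.seed(seed)
  clusters <- factor(clusters)
  rows <- match(tf_genes, rownames(layer))
  if (anyNA(rows)) stop("tf_genes must be rows of layer")
  if (!all(null_tfs %in% rownames(layer))) {
    stop("null_tfs must be rows of layer")
  }
  n_c <- ncol(layer)
  if (length(rows) > 0) {
    cm <- group_means(layer[rows, , drop = FALSE], clusters)
    act <- cm[, as.integer(clusters), drop = FALSE] +
      matrix(stats::rnorm(length(rows) * n_c, 0, noise_sd),
             nrow = length(rows))
  } else {
    act <- matrix(numeric(0), 0, n_c)
  }
  rownames(act) <- tf_genes
  n_null <- length(null_tfs)
  if (n_null > 0) {
    null_means <- matrix(stats::rnorm(n_null * nlevels(clusters)),
                         nrow = n_null)
    null_act <- null_means[, as.integer(clusters), drop = FALSE] +
      matrix(stats::rnorm(n_null * n_c, 0, noise_sd), nrow = n_null)
    rownames(null_act) <- null_tfs
    act <- rbind(act, null_act)
  }
  colnames(act) <- colnames(layer)
  act
}

`%||%` <- function(a, b) if (is.null(a)) b else a
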