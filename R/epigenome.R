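# CUT&Tag spike-in scaling, track scaling, locus signal densities, TSS
# fragment profiles and peak-proximity statistics.

#' Spike-in cell fraction from dual-genome read counts
#'
#' Read counts per species are normalized by the effective genome sizes;
#' the spike fraction is the spike share of the normalized counts:
#' `FrSpike = (spike/G_spike) / (spike/G_spike + target/G_target)`.
#'
#' @param reads_target,reads_spike Quality-filtered read counts mapped
#'   to the target and spike genomes (not both zero).
#' @param genome_size_target Effective target genome size
#'   (default mm10, 2.49e9).
#' @param genome_size_spike Effective spike genome size
#'   (default hg38, 2.86e9).
#' @return FrSpike in `[0, 1]` (vectorized).
#' @export
compute_frspike <- function(reads_target, reads_spike,
                            genome_size_target = 2.49e9,
                            genome_size_spike = 2.86e9) {
  if (any(reads_target < 0) || any(reads_spike < 0)) {
    stop("read counts must be non-negative")
  }
  if (any(reads_target + reads_spike == 0)) {
    stop("target and spike counts must not both be zero")
  }
  ns <- reads_spike / genome_size_spike
  nt <- reads_target / genome_size_target
  ns / (ns + nt)
}

#' Absolute and relative spike-in scaling factors
#'
#' `Sfabs = 1 / (RQC_total * (1 - FrSpike)) * 1 / Eff`, with
#' `Eff = RiP/RQC` of the spike-in; `Sfrel` rescales the absolute
#' factors to the maximum across samples, so the deepest-scaled sample
#' has `Sfrel = 1`.
#'
#' @param rqc_total Total quality-filtered read count per sample
#'   (target plus spike genomes).
#' @param frspike Spike-in cell fraction per sample, each below 1.
#' @param eff Assay efficiency per sample, each positive.
#' @return Data frame `sfabs`, `sfrel`.
#' @export
scaling_factors <- function(rqc_total, frspike, eff) {
  if (any(rqc_total <= 0)) stop("RQC must be positive")
  if (any(frspike >= 1)) stop("FrSpike must be below 1")
  if (any(eff <= 0)) stop("Eff must be positive")
  sfabs <- 1 / (rqc_total * (1 - frspike)) / eff
  data.frame(sfabs = sfabs, sfrel = sfabs / max(sfabs))
}

#' Scale a signal track
#'
#' @param track Data frame `chrom`, `start`, `end`, `value`.
#' @param sfrel Positive scaling factor.
#' @return Track with every value multiplied by `sfrel`.
#' @export
scale_track <- function(track, sfrel) {
  if (sfrel <= 0) stop("scaling factor must be positive")
  track$value <- track$value * sfrel
  track
}

#' Mean signal density over gene loci
#'
#' Length-weighted mean of the track value over each gene locus extended
#' by `flank` on both sides (clipped at zero); bases not covered by the
#' track count as signal 0.
#'
#' @param track Data frame `chrom`, `start`, `end`, `value` (0-based
#'   half-open, non-overlapping per chromosome).
#' @param loci Data frame `gene_id`, `chrom`, `start`, `end`.
#' @param flank Extension in bp (default 10000).
#' @return Named numeric vector of mean densities per gene.
#' @export
locus_density <- function(track, loci, flank = 10000) {
  if (any(loci$end <= loci$start)) stop("empty locus")
  out <- numeric(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    w_start <- max(0, loci$start[i] - flank)
    w_end <- loci$end[i] + flank
    seg <- track[track$chrom == loci$chrom[i] &
                   track$end > w_start & track$start < w_end, ,
                 drop = FALSE]
    total <- 0
    if (nrow(seg) > 0) {
      ov <- pmin(seg$end, w_end) - pmax(seg$start, w_start)
      total <- sum(ov * seg$value)
    }
    out[i] <- total / (w_end - w_start)
  }
  stats::setNames(out, loci$gene_id)
}

#' Strand-aware TSS fragment-end profile
#'
#' Counts fragment ends (both ends of every fragment) at each base of a
#' symmetric window around the TSS set, reverses minus-strand profiles,
#' sums over TSS, and divides by the per-group scaling factor
#' `n_cells * mean_depth`.
#'
#' @param fragments Data frame `chrom`, `start`, `end` (0-based
#'   half-open; the end coordinate of the last base is `end - 1`).
#' @param tss Data frame `chrom`, `tss`, `strand`.
#' @param window Half-window in bp (default 2000).
#' @param n_cells,mean_depth Group size and mean sequencing depth used
#'   for the scaling divisor.
#' @return Numeric vector of length `2 * window + 1`, named by offset.
#' @export
tss_profile <- function(fragments, tss, window = 2000,
                        n_cells = 1, mean_depth = 1) {
  if (nrow(tss) == 0L) stop("empty TSS set")
  prof <- numeric(2 * window + 1)
  ends <- data.frame(
    chrom = rep(fragments$chrom, 2),
    pos = c(fragments$start, fragments$end - 1L)
  )
  for (i in seq_len(nrow(tss))) {
    sel <- ends$chrom == tss$chrom[i] &
      abs(ends$pos - tss$tss[i]) <= window
    if (!any(sel)) next
    off <- ends$pos[sel] - tss$tss[i]
    if (tss$strand[i] == "-") off <- -off
    prof <- prof + tabulate(off + window + 1L, nbins = 2 * window + 1L)
  }
  names(prof) <- -window:window
  prof / (n_cells * mean_depth)
}

#' Peak counts and nearest-peak distances around TSS
#'
#' A peak is counted for a gene when its midpoint lies within
#' `[TSS - window/2, TSS + window/2)`. The nearest distance is 0 when
#' the TSS falls inside a peak and the distance to the closest peak
#' edge otherwise; `Inf` with an empty peak set.
#'
#' @param peaks Data frame `chrom`, `start`, `end` (0-based half-open),
#'   optionally `qvalue`.
#' @param tss Data frame `gene_id`, `chrom`, `tss`.
#' @param window Full window width centered on the TSS (default 20000).
#' @param q_max When `peaks$qvalue` exists, peaks at or above this q are
#'   dropped first (default 0.01).
#' @return Data frame `gene_id`, `n_peaks`, `nearest_distance`.
#' @export
peak_proximity <- function(peaks, tss, window = 20000, q_max = 0.01) {
  if (!is.null(peaks$qvalue)) {
    peaks <- peaks[peaks$qvalue < q_max, , drop = FALSE]
  }
  half <- window / 2
  n <- nrow(tss)
  counts <- integer(n)
  nearest <- rep(Inf, n)
  if (nrow(peaks) > 0) {
    mid <- (peaks$start + peaks$end) / 2
    for (i in seq_len(n)) {
      on_chr <- peaks$chrom == tss$chrom[i]
      if (!any(on_chr)) next
      t <- tss$tss[i]
      counts[i] <- sum(on_chr & mid >= t - half & mid < t + half)
      d <- ifelse(t >= peaks$start[on_chr] & t < peaks$end[on_chr], 0,
                  pmin(abs(t - peaks$start[on_chr]),
                       abs(t - peaks$end[on_chr])))
      nearest[i] <- min(d)
    }
  }
  data.frame(gene_id = tss$gene_id, n_peaks = counts,
             nearest_distance = nearest, row.names = NULL,
             stringsAsFactors = FALSE)
}
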