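# Minimal genes x cells experiment container with named layers.

#' Gene-by-cell experiment container
#'
#' Holds a raw count matrix, per-cell and per-gene annotation tables,
#' and named real-valued layers of the same shape as the counts.
#'
#' @param counts Non-negative integer genes x cells matrix with
#'   dimnames.
#' @param cell_meta Data frame with one row per cell (`cell_id`,
#'   `cluster`, `genotype`, ...).
#' @param gene_meta Data frame with one row per gene (`gene_id`,
#'   `chrom`, `tss`, ...).
#' @param layers Named list of matrices shaped like `counts`.
#' @param meta Free-form metadata (seeds, parameters).
#' @return Object of class `tec_experiment`.
#' @export
tec_experiment <- function(counts, cell_meta, gene_meta,
                           layers = list(), meta = list()) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (nrow(counts) != nrow(gene_meta)) {
    stop("gene_meta must have one row per count-matrix row")
  }
  if (ncol(counts) != nrow(cell_meta)) {
    stop("cell_meta must have one row per count-matrix column")
  }
  if (anyDuplicated(gene_meta$gene_id)) stop("gene ids must be unique")
  if (anyDuplicated(cell_meta$cell_id)) stop("cell ids must be unique")
  for (l in layers) {
    if (!all(dim(l) == dim(counts))) stop("layer dimensions must match")
  }
  structure(list(counts = counts, cells = cell_meta, genes = gene_meta,
                 layers = layers, meta = meta),
            class = "tec_experiment")
}

#' @export
print.tec_experiment <- function(x, ...) {
  cat(sprintf("tec_experiment: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  clusters: %s\n",
              paste(sort(unique(x$cells$cluster)), collapse = ", ")))
  cat(sprintf("  genotypes: %s\n",
              paste(sort(unique(x$cells$genotype)), collapse = ", ")))
  if (length(x$layers)) {
    cat(sprintf("  layers: %s\n", paste(names(x$layers), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.tec_experiment <- function(x) dim(x$counts)

#' Cell ids matching a cluster/genotype selection
#'
#' @param exp A [tec_experiment].
#' @param cluster,genotype Optional filters (vectors allowed).
#' @return Character vector of cell ids.
#' @export
cells_of <- function(exp, cluster = NULL, genotype = NULL) {
  keep <- rep(TRUE, nrow(exp$cells))
  if (!is.null(cluster)) keep <- keep & exp$cells$cluster %in% cluster
  if (!is.null(genotype)) keep <- keep & exp$cells$genotype %in% genotype
  exp$cells$cell_id[keep]
}

#' Write an experiment to a directory
#'
#' Writes `matrix.mtx` (MatrixMarket, genes x cells), `features.tsv`,
#' `barcodes.tsv`, the annotation tables, a BED-like gene table, and a
#' JSON metadata file.
#'
#' @param exp A [tec_experiment].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tec_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(exp$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(exp$genes$gene_id, file.path(dir, "features.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(exp$cells$cell_id, file.path(dir, "barcodes.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(exp$cells, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(exp$genes, file.path(dir, "gene_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = exp$genes$chrom,
                    start = exp$genes$tss,
                    end = exp$genes$tss + 1L,
                    name = exp$genes$gene_id,
                    score = 0L,
                    strand = exp$genes$strand)
  utils::write.table(bed, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(exp$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an experiment from a directory written by [write_tec_experiment()]
#'
#' @param dir Directory path.
#' @return A [tec_experiment].
#' @export
read_tec_experiment <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- utils::read.table(file.path(dir, "gene_meta.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  cells <- utils::read.table(file.path(dir, "cell_meta.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  rownames(genes) <- genes$gene_id
  rownames(cells) <- cells$cell_id
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  tec_experiment(counts, cells, genes, meta = meta)
}

#' Write a signal track as bedGraph
#'
#' Values are written with fixed precision so the files are bit-stable
#' across runs.
#' @param track Data frame `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @param digits Decimal digits for values.
#' @export
write_bedgraph <- function(track, path, digits = 6) {
  out <- data.frame(track$chrom, track$start, track$end,
                    formatC(track$value, format = "f", digits = digits))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a track data frame
#' @param path bedGraph path.
#' @return Data frame `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "value")
  df
}
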