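# Pipeline orchestration: a single configuration object carrying every
# analysis threshold with its reference default, and a deterministic
# runner writing per-stage TSV outputs plus a JSON manifest.

#' Pipeline configuration
#'
#' All thresholds default to the reference constants used throughout the
#' package: attribution significance 1e-5, z-score gap 1, connection
#' correlation 0.6, assignment floor 0.2, signature size 2000, expressed
#' quantile 0.975 at 25%, correlation read filter 5 reads in 5 cells,
#' bulk fold-change 0.5 at FDR 0.05, TRA restriction 3 organs.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param params [sim_params()] for the simulate stage.
#' @param stages Character vector of stages to run, any of
#'   `"simulate"`, `"classify"`, `"stochasticity"`, `"coexpr"`.
#' @param attribution_p,z_gap,connection_r,min_assign_r,top_k,
#'   expressed_q,expressed_frac,min_reads,min_cells,bulk_fc,bulk_fdr,
#'   max_organs Stage thresholds (reference defaults).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, params = NULL,
                       stages = c("simulate", "classify",
                                  "stochasticity", "coexpr"),
                       attribution_p = 1e-5, z_gap = 1,
                       connection_r = 0.6, min_assign_r = 0.2,
                       top_k = 2000, expressed_q = 0.975,
                       expressed_frac = 0.25, min_reads = 5,
                       min_cells = 5, bulk_fc = 0.5, bulk_fdr = 0.05,
                       max_organs = 3) {
  if (is.null(params)) params <- sim_params(seed = seed)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the analysis pipeline
#'
#' Simulates (or expects) a dataset, classifies Aire-DEGs into
#' Aire-driven and Aire-enhanced classes, computes expressing-cell
#' fractions, extracts high-correlation connections per class, and
#' writes per-stage TSV outputs with a JSON manifest recording seeds,
#' parameters and a parameter hash.
#'
#' @param cfg A [run_config()].
#' @param exp Optional pre-built [tec_experiment]; required when the
#'   simulate stage is disabled.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(cfg, exp = NULL) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  if ("simulate" %in% cfg$stages) {
    exp <- simulate_tec_dataset(cfg$params)
    write_tec_experiment(exp, file.path(cfg$out_dir, "simulate"))
  } else if (is.null(exp)) {
    stop("no input experiment and the simulate stage is disabled")
  }
  if (is.null(exp$layers$lognorm)) {
    exp$layers$lognorm <- lognormalize(exp$counts)
  }
  layer <- exp$layers$lognorm
  aire_cl <- attr(exp$cells, "aire_cluster") %||% "aire"
  ko_cl <- attr(exp$cells, "ko_counterpart") %||% "aireless"

  if ("classify" %in% cfg$stages) {
    deg <- two_group_deg(layer,
                         cells_of(exp, aire_cl, "WT"),
                         cells_of(exp, ko_cl))
    degs <- extract_aire_degs(deg)
    high_wt <- exp$cells$genotype == "WT" &
      exp$cells$cluster %in% mtec_high_clusters(exp)
    ms <- cluster_marker_stats(layer[, high_wt, drop = FALSE],
                               exp$cells$cluster[high_wt])
    attr_tab <- attribute_genes(ms$means, ms$p_adj, ms$delta,
                                p_cut = cfg$attribution_p,
                                z_gap = cfg$z_gap)
    classes <- classify_aire_degs(attr_tab, degs, aire_cl)
    out <- merge(merge(deg, attr_tab, by = "gene"), classes,
                 by = "gene")
    utils::write.table(out, file.path(cfg$out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$classification <- out
  }
  if ("stochasticity" %in% cfg$stages) {
    if (is.null(results$classification)) {
      stop("the stochasticity stage needs the classify stage")
    }
    cls <- results$classification
    driven <- cls$gene[cls$class == "aire_driven"]
    if (length(driven) > 0) {
      ft <- fraction_table(layer, driven,
                           cells_of(exp, aire_cl, "WT"),
                           q = cfg$expressed_q,
                           frac = cfg$expressed_frac)
      utils::write.table(ft, file.path(cfg$out_dir, "fractions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$fractions <- ft
    }
  }
  if ("coexpr" %in% cfg$stages) {
    if (is.null(results$classification)) {
      stop("the coexpr stage needs the classify stage")
    }
    cls <- results$classification
    conns <- list()
    for (cl_name in c("aire_driven", "aire_enhanced")) {
      genes <- cls$gene[cls$class == cl_name]
      cells <- if (cl_name == "aire_driven") {
        c(cells_of(exp, aire_cl), cells_of(exp, ko_cl))
      } else {
        cells_of(exp, grep("^m", unique(exp$cells$cluster), value = TRUE))
      }
      genes <- intersect(genes,
                         filter_correlation_genes(exp$counts, cells,
                                                  cfg$min_reads,
                                                  cfg$min_cells))
      if (length(genes) < 2) next
      cm <- correlation_matrix(layer, genes, cells)
      conns[[cl_name]] <- extract_connections(cm, exp$genes,
                                              cfg$connection_r)
      utils::write.table(conns[[cl_name]],
                         file.path(cfg$out_dir,
                                   paste0("connections_", cl_name,
                                          ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    results$connections <- conns
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("aireclass")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameter_hash = config_hash(cfg),
    timestamp_free = TRUE
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

# mTEC-high cluster set of an experiment: the Aire cluster, its
# counterpart, the transit-amplifying cluster and the mimetic clusters.
mtec_high_clusters <- function(exp) {
  cl <- unique(exp$cells$cluster)
  setdiff(cl, "low")
}

# stable hash of the configuration (djb2 over the serialized fields)
config_hash <- function(cfg) {
  flat <- cfg[setdiff(names(cfg), "out_dir")]
  txt <- paste(utils::capture.output(utils::str(flat)), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(txt)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
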