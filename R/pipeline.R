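#' Methylation-driven path analysis of one cancer cohort
#'
#' End-to-end analysis of one paired tumor/normal cohort. Per-CpG
#' differential methylation is collapsed to one representative change per
#' gene ([summarize_methylation()]); the signed interaction network is
#' filtered to high-confidence human activation/inhibition edges
#' ([filter_edges()], [build_graph()]); catalog oncogenes/suppressors with
#' concordant significant expression changes become driver genes
#' ([annotate_drivers()]); and a breadth-first sign-consistent search
#' ([search_paths()]) finds, for every driver, the shortest paths to genes
#' whose methylation change exceeds the baseline threshold and is inversely
#' related to their expression. Results are summarized separately for the
#' large class (absolute change above `meth_threshold`) and the normal
#' class (between `baseline_threshold` and `meth_threshold`).
#'
#' `meth_threshold` defaults to the constant 32.2 (percent) used as the
#' operating large-change cutoff; pass `meth_threshold = "fit"` to derive it
#' from the data at hand via [fit_cauchy()] on the absolute representative
#' changes (the formula value `center + 2 * scale`).
#'
#' @param cpg_table per-CpG differential methylation table (see
#'   [summarize_methylation()]), or an already summarized gene-level table
#'   (one row per gene; detected by the absence of duplicate genes plus a
#'   `trend` column).
#' @param expression_table per-gene expression table (`gene`, `log2fc`,
#'   `fdr`).
#' @param network either a prebuilt `interaction_graph`, or a raw/parsed
#'   edge table to be filtered with `min_score`/`taxon` and built.
#' @param driver_catalog data.frame (`gene`, `role`).
#' @param dataset cohort label used in the summary rows.
#' @param meth_threshold large methylation change threshold in percent, or
#'   `"fit"`. Default 32.2.
#' @param baseline_threshold normal methylation change threshold in
#'   percent. Default 15.
#' @param maf_cutoff SNP MAF probe filter cutoff. Default 0.05.
#' @param fdr_cutoff significance cutoff for methylation and expression.
#'   Default 0.1.
#' @param fc_threshold linear fold-change threshold. Default 2.
#' @param min_score minimum interaction confidence score. Default 800.
#' @param taxon taxon kept by the edge filter. Default `"9606"`.
#' @param max_depth maximum path length in edges. Default 7.
#' @param close_steps distance counted as "close". Default 3.
#' @param strict apply the fold-change magnitude rule to intermediate path
#'   nodes. Default FALSE.
#' @return object of class `meth_driver_analysis`: list with `dataset`,
#'   `gene_meth`, `drivers`, `graph`, `paths` (all shortest per
#'   driver-terminal pair, searched at the baseline threshold),
#'   `driver_paths` (per-driver shortest retention), `summary` (one row per
#'   methylation class), `class_counts`, `cauchy_fit` (when fitted),
#'   `thresholds`, and `call`.
#' @export
meth_driver_analysis <- function(cpg_table, expression_table, network,
                                 driver_catalog, dataset = "cohort",
                                 meth_threshold = 32.2,
                                 baseline_threshold = 15,
                                 maf_cutoff = 0.05, fdr_cutoff = 0.1,
                                 fc_threshold = 2, min_score = 800,
                                 taxon = "9606", max_depth = 7,
                                 close_steps = 3, strict = FALSE) {
  already_gene_level <- "trend" %in% names(cpg_table) &&
    !anyDuplicated(cpg_table$gene)
  gene_meth <- if (already_gene_level) {
    cpg_table
  } else {
    summarize_methylation(cpg_table, maf_cutoff = maf_cutoff,
                          fdr_cutoff = fdr_cutoff)
  }

  fit <- NULL
  if (identical(meth_threshold, "fit")) {
    fit <- fit_cauchy(abs(gene_meth$delta_beta_pct))
    meth_threshold <- large_change_threshold(fit)
  }
  if (!is.numeric(meth_threshold) || meth_threshold <= baseline_threshold) {
    stop("'meth_threshold' must be numeric and above 'baseline_threshold'")
  }

  graph <- if (inherits(network, "interaction_graph")) {
    network
  } else {
    edges <- if (all(c("gene_a", "gene_b", "mode", "score") %in%
                       names(network))) {
      if (!"sign" %in% names(network)) {
        network$sign <- ifelse(
          network$mode %in% c("activation", "inhibition"),
          network$mode, NA_character_)
      }
      if (!"taxon" %in% names(network)) network$taxon <- NA_character_
      network
    } else {
      parse_edges(network)
    }
    build_graph(filter_edges(edges, min_score = min_score, taxon = taxon))
  }

  drivers <- annotate_drivers(expression_table, driver_catalog,
                              fc_threshold = fc_threshold,
                              fdr_cutoff = fdr_cutoff)
  paths <- search_paths(graph, drivers, gene_meth, expression_table,
                        meth_threshold = baseline_threshold,
                        fc_threshold = fc_threshold,
                        fdr_cutoff = fdr_cutoff, max_depth = max_depth,
                        strict = strict)

  sets <- class_gene_sets(gene_meth, expression_table,
                          threshold = meth_threshold,
                          baseline = baseline_threshold,
                          fc_threshold = fc_threshold,
                          fdr_cutoff = fdr_cutoff)
  summ <- rbind(
    cbind(dataset = dataset, meth_class = "large",
          summarize_distances(paths, sets$large, close_steps = close_steps)),
    cbind(dataset = dataset, meth_class = "normal",
          summarize_distances(paths, sets$normal, close_steps = close_steps))
  )
  rownames(summ) <- NULL

  structure(
    list(dataset = dataset,
         gene_meth = gene_meth,
         drivers = drivers,
         graph = graph,
         paths = paths,
         driver_paths = shortest_retention(paths),
         summary = summ,
         class_counts = class_counts(gene_meth, expression_table,
                                     threshold = meth_threshold,
                                     baseline = baseline_threshold,
                                     fc_threshold = fc_threshold,
                                     fdr_cutoff = fdr_cutoff),
         cauchy_fit = fit,
         thresholds = c(large = meth_threshold,
                        baseline = baseline_threshold),
         call = match.call()),
    class = "meth_driver_analysis"
  )
}

#' @export
print.meth_driver_analysis <- function(x, ...) {
  cat("Methylation-driven path analysis:", x$dataset, "\n")
  cat(sprintf("  thresholds: large > %.4g%%, baseline > %.4g%%\n",
              x$thresholds["large"], x$thresholds["baseline"]))
  cat(sprintf("  %d genes with a representative methylation change\n",
              nrow(x$gene_meth)))
  cat(sprintf("  class counts: %d large, %d normal\n",
              x$class_counts["n_large"], x$class_counts["n_normal"]))
  nd <- sum(x$drivers$dysregulated)
  cat(sprintf("  %d of %d catalog genes dysregulated (driver genes)\n",
              nd, nrow(x$drivers)))
  cat(sprintf("  %d methylation-driven paths to %d distinct genes\n",
              nrow(x$paths), length(unique(x$paths$terminal))))
  cat("Per-class distance summary:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.meth_driver_analysis <- function(object, ...) {
  object$summary
}
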