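#' Randomization null for close methylation-driven interactions
#'
#' Empirical null for the close-interaction counts: per replicate,
#' `n_select` genes are drawn without replacement from the pool of
#' differentially altered genes (genes passing both the differential
#' expression and differential methylation screens), treated as the
#' candidate terminal set, and the number of them that reach any
#' dysregulated driver within `steps` interaction edges under the unchanged
#' path constraints (sign-consistent edges through significantly
#' differentially expressed nodes; fold-change magnitude and, when a
#' methylation table is supplied, inverse methylation/expression sign at the
#' candidate itself) is recorded. A single integer seed controls the whole
#' run through per-replicate substream seeds, so results are reproducible
#' and replicates are independent.
#'
#' @param graph an `interaction_graph`.
#' @param drivers annotated driver data.frame (see [annotate_drivers()]) or
#'   character vector of dysregulated driver genes.
#' @param altered_gene_pool character vector to sample from.
#' @param n_select genes drawn per replicate (without replacement).
#' @param n_reps number of replicates. Default 100.
#' @param seed integer master seed. Default 1.
#' @param expression_table expression table (`gene`, `log2fc`, `fdr`).
#' @param meth_table optional gene-level methylation table; when given, a
#'   selected gene only counts if its methylation change is significant and
#'   sign-opposed to its expression change.
#' @param fc_threshold linear fold-change threshold. Default 2.
#' @param fdr_cutoff significance cutoff. Default 0.1.
#' @param steps maximum distance counted as reaching a driver. Default 3.
#' @return object of class `randomization_result`: list with `counts` (one
#'   per replicate), `n_reps`, `n_select`, `seed`, `mean_count`,
#'   `max_count`, `frac_reps_with_hit`.
#' @export
random_path_test <- function(graph, drivers, altered_gene_pool, n_select,
                             n_reps = 100, seed = 1, expression_table,
                             meth_table = NULL, fc_threshold = 2,
                             fdr_cutoff = 0.1, steps = 3) {
  altered_gene_pool <- unique(altered_gene_pool)
  if (n_select > length(altered_gene_pool)) {
    stop("'n_select' (", n_select, ") exceeds the pool size (",
         length(altered_gene_pool), ")")
  }
  if (n_reps < 1L) stop("'n_reps' must be at least 1")
  driver_genes <- if (is.data.frame(drivers)) {
    drivers$gene[drivers$dysregulated]
  } else {
    as.character(drivers)
  }

  st <- .expression_state(expression_table, fdr_cutoff)
  sources <- intersect(driver_genes, intersect(graph$nodes, names(st$dir)))

  # Reachability and the per-gene constraints do not depend on which genes
  # are selected, so the qualifying set is computed once.
  reachable <- character()
  if (length(sources) > 0L) {
    bfs <- .signed_bfs(graph, sources, st$dir, max_depth = steps,
                       collect_parents = FALSE)
    reachable <- ls(bfs$dist)
  }
  qualifying <- intersect(altered_gene_pool, reachable)
  lfc_cut <- log2(fc_threshold)
  qualifying <- qualifying[st$mag[qualifying] >= lfc_cut]
  qualifying <- qualifying[!is.na(qualifying)]
  if (!is.null(meth_table)) {
    mi <- match(qualifying, meth_table$gene)
    ei <- match(qualifying, expression_table$gene)
    inv <- !is.na(mi) &
      meth_table$fdr[mi] < fdr_cutoff &
      sign(meth_table$delta_beta_pct[mi]) ==
        -sign(expression_table$log2fc[ei])
    qualifying <- qualifying[inv]
  }

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  counts <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(rep_seeds[i])
    sel <- sample(altered_gene_pool, n_select)
    counts[i] <- sum(sel %in% qualifying)
  }
  structure(
    list(counts = counts, n_reps = n_reps, n_select = n_select, seed = seed,
         steps = steps,
         n_qualifying_in_pool = length(qualifying),
         mean_count = mean(counts), max_count = max(counts),
         frac_reps_with_hit = mean(counts > 0)),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat("Randomization null for close driver interactions\n")
  cat(sprintf("  %d replicates, %d genes selected per replicate, seed %d\n",
              x$n_reps, x$n_select, x$seed))
  cat(sprintf("  genes reaching a driver within %d steps per replicate:\n",
              x$steps))
  cat(sprintf("    mean %.3f, max %d, replicates with any hit: %.0f%%\n",
              x$mean_count, x$max_count, 100 * x$frac_reps_with_hit))
  invisible(x)
}
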