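# Shared fixtures and the independent path-search oracle.

make_expr <- function(genes, log2fc, fdr = 0.01) {
  data.frame(gene = genes, log2fc = log2fc,
             fdr = rep_len(fdr, length(genes)), stringsAsFactors = FALSE)
}

make_meth <- function(genes, delta, fdr = 0.01) {
  data.frame(gene = genes, delta_beta_pct = delta,
             fdr = rep_len(fdr, length(genes)),
             trend = ifelse(delta > 0, "up", "down"),
             representative_cpg = paste0(genes, "_cg01"),
             region = "TSS200", stringsAsFactors = FALSE)
}

make_edges <- function(a, b, sign) {
  data.frame(gene_a = a, gene_b = b, mode = sign, sign = sign,
             score = 900L, taxon = "9606", is_directional = "f",
             stringsAsFactors = FALSE)
}

# A random test case for oracle-equivalence checks: a small multigraph with
# random signs, random expression directions/magnitudes/significance and
# random methylation changes over <= n_nodes genes.
random_search_case <- function(seed, n_nodes = 10, n_edges = 16) {
  set.seed(seed)
  genes <- paste0("N", seq_len(n_nodes))
  a <- sample(genes, n_edges, replace = TRUE)
  b <- sample(genes, n_edges, replace = TRUE)
  keep <- a != b
  edges <- make_edges(a[keep], b[keep],
                      sample(c("activation", "inhibition"), sum(keep),
                             replace = TRUE))
  expr <- make_expr(
    genes,
    log2fc = round(runif(n_nodes, -3, 3), 2),
    fdr = ifelse(runif(n_nodes) < 0.8, 0.01, 0.5))
  meth <- make_meth(
    genes,
    delta = round(runif(n_nodes, -80, 80), 1),
    fdr = ifelse(runif(n_nodes) < 0.8, 0.01, 0.5))
  driver <- sample(genes, 1)
  # force the driver to look dysregulated so searches actually start
  expr$log2fc[expr$gene == driver] <- sample(c(-2.5, 2.5), 1)
  expr$fdr[expr$gene == driver] <- 0.01
  list(edges = edges, expr = expr, meth = meth, driver = driver)
}

# Independent oracle: exhaustive enumeration of all simple paths of length
# <= max_depth with igraph, then direct application of the predicates.
# Returns minimal qualifying distance per terminal (named integer vector).
oracle_min_distances <- function(case, meth_threshold, max_depth = 7,
                                 fc_threshold = 2, fdr_cutoff = 0.1) {
  expr <- case$expr
  meth <- case$meth
  dir <- ifelse(expr$log2fc > 0, "up", "down")
  names(dir) <- expr$gene
  eligible <- expr$gene[expr$fdr < fdr_cutoff & expr$log2fc != 0]

  driven <- methylation_driven(meth$gene, meth, expr,
                               meth_threshold = meth_threshold,
                               fc_threshold = fc_threshold,
                               fdr_cutoff = fdr_cutoff)
  terminals <- names(driven)[driven]

  pair_key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  sign_lookup <- split(case$edges$sign,
                       pair_key(case$edges$gene_a, case$edges$gene_b))

  simple <- unique(case$edges[c("gene_a", "gene_b")])
  simple <- simple[simple$gene_a != simple$gene_b, ]
  g <- igraph::graph_from_data_frame(simple, directed = FALSE)

  out <- stats::setNames(integer(0), character(0))
  if (!case$driver %in% eligible) return(out)
  if (case$driver %in% terminals) out[case$driver] <- 0L
  if (!case$driver %in% igraph::V(g)$name) return(out)
  for (t in setdiff(terminals, case$driver)) {
    if (!t %in% igraph::V(g)$name) next
    paths <- igraph::all_simple_paths(g, from = case$driver, to = t,
                                      cutoff = max_depth)
    best <- NA_integer_
    for (p in paths) {
      nodes <- igraph::V(g)$name[p]
      if (!all(nodes %in% eligible)) next
      ok <- TRUE
      for (k in seq_len(length(nodes) - 1)) {
        u <- nodes[k]; v <- nodes[k + 1]
        req <- if (dir[[u]] == dir[[v]]) "activation" else "inhibition"
        if (!req %in% sign_lookup[[pair_key(u, v)]]) { ok <- FALSE; break }
      }
      if (ok) best <- min(best, length(nodes) - 1L, na.rm = TRUE)
    }
    if (!is.na(best)) out[t] <- best
  }
  out
}

# Package-side minimal distances in the same shape as the oracle.
package_min_distances <- function(case, meth_threshold, max_depth = 7) {
  g <- build_graph(case$edges)
  paths <- suppressMessages(
    search_from_driver(g, case$driver, case$meth, case$expr,
                       meth_threshold = meth_threshold,
                       max_depth = max_depth))
  if (nrow(paths) == 0) return(stats::setNames(integer(0), character(0)))
  res <- tapply(paths$distance, paths$terminal, min)
  out <- as.integer(res)
  names(out) <- names(res)
  out[order(names(out))]
}

cascade_config <- function(distances = c(0, 1, 2, 3, 5), n_genes = 200,
                           background_edge_count = 80) {
  simulation_config(
    n_genes = n_genes,
    background_edge_count = background_edge_count,
    n_drivers = length(distances),
    planted_cascades = lapply(seq_along(distances), function(i) {
      d <- distances[i]
      list(driver = sprintf("DRV%02d", i), distance = d,
           signs = sample(c("activation", "inhibition"), d, replace = TRUE))
    })
  )
}
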