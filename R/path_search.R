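#' Annotate dysregulated cancer driver genes
#'
#' A catalog oncogene is a driver when its expression is significantly *up*
#' (fold-change at least `fc_threshold`, i.e. `log2fc >= log2(fc_threshold)`,
#' FDR below the cutoff); a catalog tumor suppressor is a driver when its
#' expression is significantly *down* (`log2fc <= -log2(fc_threshold)`).
#' Catalog genes absent from the expression table are skipped and counted.
#'
#' @param expression_table data.frame with columns `gene`, `log2fc`, `fdr`.
#' @param driver_catalog data.frame with columns `gene` and `role`
#'   (`"oncogene"` or `"suppressor"`).
#' @param fc_threshold linear fold-change threshold. Default 2.
#' @param fdr_cutoff expression significance cutoff. Default 0.1.
#' @return data.frame with one row per catalog gene found in the expression
#'   table: `gene`, `role`, `log2fc`, `fdr`, `dysregulated`, `direction`
#'   (`"up"`/`"down"` for dysregulated drivers, NA otherwise). Skipped count
#'   in attribute `n_missing`.
#' @export
annotate_drivers <- function(expression_table, driver_catalog,
                             fc_threshold = 2, fdr_cutoff = 0.1) {
  if (!all(driver_catalog$role %in% c("oncogene", "suppressor"))) {
    stop("driver catalog roles must be 'oncogene' or 'suppressor'")
  }
  idx <- match(driver_catalog$gene, expression_table$gene)
  missing <- is.na(idx)
  if (any(missing)) {
    message(sum(missing),
            " catalog gene(s) absent from the expression table; skipped")
  }
  cat_found <- driver_catalog[!missing, , drop = FALSE]
  idx <- idx[!missing]
  log2fc <- expression_table$log2fc[idx]
  fdr <- expression_table$fdr[idx]
  lfc_cut <- log2(fc_threshold)
  sig <- fdr < fdr_cutoff
  dys <- ifelse(cat_found$role == "oncogene",
                sig & log2fc >= lfc_cut,
                sig & log2fc <= -lfc_cut)
  out <- data.frame(
    gene = cat_found$gene,
    role = cat_found$role,
    log2fc = log2fc,
    fdr = fdr,
    dysregulated = dys,
    direction = ifelse(dys,
                       ifelse(cat_found$role == "oncogene", "up", "down"),
                       NA_character_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_missing") <- sum(missing)
  out
}

#' Sign consistency of one interaction edge
#'
#' Along an activation edge the two genes' expression directions must agree;
#' along an inhibition edge they must oppose. Vectorized over all arguments.
#'
#' @param sign `"activation"` or `"inhibition"`.
#' @param dir_u,dir_v expression directions, `"up"` or `"down"`.
#' @return logical.
#' @examples
#' edge_consistent("activation", "up", "up")    # TRUE
#' edge_consistent("inhibition", "up", "up")    # FALSE
#' edge_consistent("inhibition", "up", "down")  # TRUE
#' @export
edge_consistent <- function(sign, dir_u, dir_v) {
  if (!all(sign %in% c("activation", "inhibition"))) {
    stop("'sign' must be 'activation' or 'inhibition'")
  }
  if (!all(c(dir_u, dir_v) %in% c("up", "down"))) {
    stop("directions must be 'up' or 'down'")
  }
  ifelse(sign == "activation", dir_u == dir_v, dir_u != dir_v)
}

#' Is a gene methylation-driven?
#'
#' A gene qualifies when (i) its representative absolute methylation change
#' exceeds `meth_threshold` (percent), (ii) the methylation change is
#' significant (FDR below the cutoff), (iii) methylation and expression
#' changes are inversely related (opposite signs), and (iv) the expression
#' change is of sufficient magnitude (`|log2fc| >= log2(fc_threshold)`).
#' Genes missing from either table return FALSE.
#'
#' @param genes character vector of gene symbols.
#' @param meth_table gene-level methylation data.frame
#'   (from [summarize_methylation()]; columns `gene`, `delta_beta_pct`,
#'   `fdr`).
#' @param expression_table data.frame with `gene`, `log2fc`, `fdr`.
#' @param meth_threshold methylation change threshold in percent.
#'   Default 32.2.
#' @param fc_threshold linear fold-change threshold. Default 2.
#' @param fdr_cutoff significance cutoff for both tables. Default 0.1.
#' @return named logical vector, one element per input gene.
#' @export
methylation_driven <- function(genes, meth_table, expression_table,
                               meth_threshold = 32.2, fc_threshold = 2,
                               fdr_cutoff = 0.1) {
  mi <- match(genes, meth_table$gene)
  ei <- match(genes, expression_table$gene)
  dmeth <- meth_table$delta_beta_pct[mi]
  mfdr <- meth_table$fdr[mi]
  l2fc <- expression_table$log2fc[ei]
  efdr <- expression_table$fdr[ei]
  ok <- !is.na(mi) & !is.na(ei) &
    abs(dmeth) > meth_threshold &
    mfdr < fdr_cutoff &
    efdr < fdr_cutoff &
    sign(dmeth) == -sign(l2fc) &
    abs(l2fc) >= log2(fc_threshold)
  ok[is.na(ok)] <- FALSE
  names(ok) <- genes
  ok
}

# Expression state used by the traversal: direction and magnitude of every
# significantly differentially expressed gene (nonzero, finite log2fc).
.expression_state <- function(expression_table, fdr_cutoff = 0.1) {
  keep <- is.finite(expression_table$log2fc) &
    expression_table$log2fc != 0 &
    expression_table$fdr < fdr_cutoff
  list(
    dir = stats::setNames(
      ifelse(expression_table$log2fc[keep] > 0, "up", "down"),
      expression_table$gene[keep]),
    mag = stats::setNames(abs(expression_table$log2fc[keep]),
                          expression_table$gene[keep])
  )
}

# Breadth-first distances and predecessor lists over the sign-consistent,
# differentially-expressed subgraph. `sources` start at distance 0. Returns
# dist (named integer vector) and parents (named list of predecessor sets).
.signed_bfs <- function(graph, sources, dirs, max_depth,
                        collect_parents = TRUE) {
  dist <- new.env(parent = emptyenv())
  parents <- new.env(parent = emptyenv())
  frontier <- unique(sources)
  for (s in frontier) assign(s, 0L, envir = dist)
  d <- 0L
  while (length(frontier) > 0L && d < max_depth) {
    nxt <- character()
    for (u in frontier) {
      nb <- graph$adj[[u]]
      if (is.null(nb) || nrow(nb) == 0L) next
      du <- dirs[[u]]
      vdir <- dirs[nb$neighbor]
      req <- ifelse(vdir == du, "activation", "inhibition")
      ok <- !is.na(vdir) & nb$sign == req
      for (v in unique(nb$neighbor[ok])) {
        dv <- get0(v, envir = dist, inherits = FALSE)
        if (is.null(dv)) {
          assign(v, d + 1L, envir = dist)
          if (collect_parents) assign(v, u, envir = parents)
          nxt <- c(nxt, v)
        } else if (collect_parents && dv == d + 1L) {
          assign(v, c(get(v, envir = parents), u), envir = parents)
        }
      }
    }
    frontier <- unique(nxt)
    d <- d + 1L
  }
  list(dist = dist, parents = parents)
}

# Enumerate all shortest paths (as node vectors) from a source to `node`
# using the BFS predecessor DAG; capped at `limit` paths.
.enumerate_paths <- function(node, sources, parents, limit) {
  if (node %in% sources) return(list(node))
  ps <- get0(node, envir = parents, inherits = FALSE)
  if (is.null(ps)) return(list())
  out <- list()
  for (p in ps) {
    sub <- .enumerate_paths(p, sources, parents, limit - length(out))
    for (s in sub) {
      out[[length(out) + 1L]] <- c(s, node)
      if (length(out) >= limit) return(out)
    }
  }
  out
}

#' Breadth-first search for methylation-driven paths from one driver
#'
#' Starting from a dysregulated driver gene, the traversal expands level by
#' level through the interaction graph up to `max_depth` (the driver's 7th
#' neighbors by default). A path may extend across an edge only when the
#' neighbor is significantly differentially expressed and the edge sign is
#' consistent with the two genes' expression directions (activation: same
#' direction; inhibition: opposite). Every node satisfying the
#' methylation-driven predicate ([methylation_driven()]) at the given
#' threshold ends a reported path there; for each (driver, terminal) pair
#' all paths at the minimal distance are returned (equally short parallel
#' routes are all included). The driver itself being methylation-driven
#' yields a distance-0 path.
#'
#' By default the fold-change *magnitude* requirement applies at the driver
#' and the terminal only; intermediates must merely be significantly
#' differentially expressed in a consistent direction. `strict = TRUE`
#' applies the magnitude rule to intermediates too.
#'
#' @param graph an `interaction_graph`.
#' @param driver driver gene symbol (should be dysregulated; see
#'   [annotate_drivers()]).
#' @param meth_table gene-level methylation table.
#' @param expression_table expression table (`gene`, `log2fc`, `fdr`).
#' @param meth_threshold methylation change threshold (percent).
#'   Default 32.2.
#' @param fc_threshold linear fold-change threshold. Default 2.
#' @param fdr_cutoff significance cutoff. Default 0.1.
#' @param max_depth maximum number of interaction steps. Default 7.
#' @param strict apply the fold-change magnitude rule to intermediate nodes.
#'   Default FALSE.
#' @param path_limit cap on enumerated equal-length paths per terminal;
#'   exceeding it sets attribute `truncated`. Default 1000.
#' @param drivers optional character vector of all driver genes, used to
#'   flag paths passing through another driver (`via_driver`).
#' @return data.frame of paths: `driver`, `terminal`, `distance`, `nodes`
#'   (gene chain joined by `"_"`), `signs` (edge-sign chain joined by
#'   `"_"`), `via_driver`.
#' @export
search_from_driver <- function(graph, driver, meth_table, expression_table,
                               meth_threshold = 32.2, fc_threshold = 2,
                               fdr_cutoff = 0.1, max_depth = 7,
                               strict = FALSE, path_limit = 1000,
                               drivers = NULL) {
  empty <- data.frame(driver = character(), terminal = character(),
                      distance = integer(), nodes = character(),
                      signs = character(), via_driver = logical(),
                      stringsAsFactors = FALSE)
  st <- .expression_state(expression_table, fdr_cutoff)
  if (!driver %in% names(st$dir)) {
    message("driver '", driver,
            "' is not significantly differentially expressed")
    return(empty)
  }
  dirs <- st$dir
  if (strict) {
    lfc_cut <- log2(fc_threshold)
    keep <- st$mag >= lfc_cut | names(st$mag) == driver
    dirs <- dirs[keep]
  }
  driven <- methylation_driven(meth_table$gene, meth_table, expression_table,
                               meth_threshold = meth_threshold,
                               fc_threshold = fc_threshold,
                               fdr_cutoff = fdr_cutoff)
  terminals <- names(driven)[driven]

  if (!driver %in% graph$nodes) {
    # an isolated driver can still be its own distance-0 terminal
    if (driver %in% terminals) {
      out <- data.frame(driver = driver, terminal = driver, distance = 0L,
                        nodes = driver, signs = "",
                        via_driver = if (is.null(drivers)) NA else FALSE,
                        stringsAsFactors = FALSE)
      attr(out, "truncated") <- FALSE
      return(out)
    }
    message("driver '", driver, "' is absent from the interaction graph")
    return(empty)
  }

  bfs <- .signed_bfs(graph, driver, dirs, max_depth)
  reached <- intersect(terminals, ls(bfs$dist))
  if (length(reached) == 0L) return(empty)

  rows <- list()
  truncated <- FALSE
  for (t in sort(reached)) {
    paths <- .enumerate_paths(t, driver, bfs$parents, path_limit)
    if (length(paths) >= path_limit) truncated <- TRUE
    for (p in paths) {
      n <- length(p)
      sg <- if (n > 1L) {
        ifelse(dirs[p[-n]] == dirs[p[-1L]], "activation", "inhibition")
      } else {
        character()
      }
      via <- if (is.null(drivers)) NA else
        any(p[-c(1L, n)] %in% drivers)
      rows[[length(rows) + 1L]] <- data.frame(
        driver = driver, terminal = t, distance = n - 1L,
        nodes = paste(p, collapse = "_"),
        signs = paste(sg, collapse = "_"),
        via_driver = via, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  out
}

#' Search methylation-driven paths from every dysregulated driver
#'
#' Convenience loop over [search_from_driver()] for all dysregulated rows of
#' an annotated driver table (or a plain character vector of driver genes).
#'
#' @param graph an `interaction_graph`.
#' @param drivers annotated driver data.frame from [annotate_drivers()], or
#'   a character vector of driver gene symbols.
#' @inheritParams search_from_driver
#' @return combined path data.frame (see [search_from_driver()]).
#' @export
search_paths <- function(graph, drivers, meth_table, expression_table,
                         meth_threshold = 32.2, fc_threshold = 2,
                         fdr_cutoff = 0.1, max_depth = 7, strict = FALSE,
                         path_limit = 1000) {
  driver_genes <- if (is.data.frame(drivers)) {
    drivers$gene[drivers$dysregulated]
  } else {
    as.character(drivers)
  }
  pieces <- lapply(driver_genes, function(d) {
    search_from_driver(graph, d, meth_table, expression_table,
                       meth_threshold = meth_threshold,
                       fc_threshold = fc_threshold,
                       fdr_cutoff = fdr_cutoff, max_depth = max_depth,
                       strict = strict, path_limit = path_limit,
                       drivers = driver_genes)
  })
  pieces <- Filter(function(p) nrow(p) > 0L, pieces)
  if (length(pieces) == 0L) {
    return(data.frame(driver = character(), terminal = character(),
                      distance = integer(), nodes = character(),
                      signs = character(), via_driver = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Keep only each driver's shortest methylation-driven paths
#'
#' Per driver, the minimal observed distance is kept and all paths at that
#' distance are retained (several equally short paths are all reported);
#' longer paths are discarded.
#'
#' @param paths path data.frame (from [search_paths()]).
#' @return filtered path data.frame.
#' @export
shortest_retention <- function(paths) {
  if (nrow(paths) == 0L) return(paths)
  min_d <- tapply(paths$distance, paths$driver, min)
  keep <- paths$distance == min_d[paths$driver]
  out <- paths[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance summary for a methylation class
#'
#' Summarizes, for a given set of class genes (e.g. all genes whose
#' methylation change exceeds the large-change threshold), how many reach a
#' driver gene at all, how many are "close" (within `close_steps`
#' interaction steps), the close proportion, and the mean per-gene minimal
#' distance over the close genes (NA when none are close; optionally the
#' mean over all reached genes via `avg_over = "reached"`).
#'
#' @param paths path data.frame from [search_paths()] (any driver, any
#'   distance up to the search depth).
#' @param class_gene_set character vector of genes in the methylation class.
#' @param close_steps distance counted as "close". Default 3.
#' @param avg_over average the distance over `"close"` genes (default) or
#'   all `"reached"` genes.
#' @return one-row data.frame: `n_class_genes`, `n_with_path`, `n_close`,
#'   `close_proportion`, `avg_distance`.
#' @export
summarize_distances <- function(paths, class_gene_set, close_steps = 3,
                                avg_over = c("close", "reached")) {
  avg_over <- match.arg(avg_over)
  class_gene_set <- unique(class_gene_set)
  sub <- paths[paths$terminal %in% class_gene_set, , drop = FALSE]
  n_class <- length(class_gene_set)
  if (nrow(sub) == 0L) {
    return(data.frame(n_class_genes = n_class, n_with_path = 0L,
                      n_close = 0L, close_proportion = 0,
                      avg_distance = NA_real_))
  }
  per_gene_min <- tapply(sub$distance, sub$terminal, min)
  n_with <- length(per_gene_min)
  close <- per_gene_min <= close_steps
  n_close <- sum(close)
  avg <- if (avg_over == "close") {
    if (n_close > 0L) mean(per_gene_min[close]) else NA_real_
  } else {
    mean(per_gene_min)
  }
  data.frame(n_class_genes = n_class, n_with_path = n_with,
             n_close = n_close,
             close_proportion = n_close / n_with,
             avg_distance = avg)
}
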