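#' Parse a STRING-actions-style edge table
#'
#' Converts a raw actions table (one row per reported interaction, with an
#' interaction `mode`, an integer combined confidence `score` on 0-1000, and
#' optionally a species/taxon column) into a normalized edge list. Rows with
#' a missing protein identifier or an unparseable score are skipped and
#' counted. Duplicate pairs are kept; deduplication happens in
#' [build_graph()].
#'
#' @param table data.frame of raw rows.
#' @param columns named character vector mapping the roles `a`, `b`, `mode`,
#'   `score`, and optionally `taxon` and `directional` to column names in
#'   `table`.
#' @return data.frame with columns `gene_a`, `gene_b`, `mode`, `sign`
#'   (`"activation"`/`"inhibition"` when the mode is one of those, else NA),
#'   `score`, `taxon`, `is_directional`; skipped-row count in attribute
#'   `n_skipped`.
#' @export
parse_edges <- function(table,
                        columns = c(a = "item_id_a", b = "item_id_b",
                                    mode = "mode", score = "score",
                                    taxon = "taxon",
                                    directional = "is_directional")) {
  required <- c("a", "b", "mode", "score")
  for (role in required) {
    col <- columns[[role]]
    if (is.null(col) || is.na(col) || !col %in% names(table)) {
      stop("required column missing from the actions table: '",
           if (is.null(col) || is.na(col)) role else col, "'")
    }
  }
  a <- as.character(table[[columns[["a"]]]])
  b <- as.character(table[[columns[["b"]]]])
  mode <- as.character(table[[columns[["mode"]]]])
  score <- suppressWarnings(as.integer(table[[columns[["score"]]]]))
  taxon <- if (!is.na(columns["taxon"]) &&
               columns[["taxon"]] %in% names(table)) {
    as.character(table[[columns[["taxon"]]]])
  } else {
    rep(NA_character_, nrow(table))
  }
  directional <- if (!is.na(columns["directional"]) &&
                     columns[["directional"]] %in% names(table)) {
    as.character(table[[columns[["directional"]]]])
  } else {
    rep(NA_character_, nrow(table))
  }
  bad <- is.na(a) | a == "" | is.na(b) | b == "" | is.na(score) |
    is.na(mode) | mode == ""
  out <- data.frame(
    gene_a = a[!bad], gene_b = b[!bad], mode = mode[!bad],
    sign = ifelse(mode[!bad] %in% c("activation", "inhibition"),
                  mode[!bad], NA_character_),
    score = score[!bad], taxon = taxon[!bad],
    is_directional = directional[!bad],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(bad)
  if (any(bad)) message(sum(bad), " unparseable row(s) skipped")
  out
}

#' Read a STRING-actions-style TSV
#'
#' @param path path to a tab-separated actions file with a header row.
#' @param columns column-role mapping, as in [parse_edges()].
#' @param ... further arguments to [utils::read.delim()].
#' @return normalized edge data.frame (see [parse_edges()]).
#' @export
read_string_actions <- function(path,
                                columns = c(a = "item_id_a", b = "item_id_b",
                                            mode = "mode", score = "score",
                                            taxon = "taxon",
                                            directional = "is_directional"),
                                ...) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, ...)
  parse_edges(raw, columns = columns)
}

#' High-confidence signed-edge filter
#'
#' Keeps only the interaction types whose direction of effect is defined
#' (activation and inhibition by default), drops low- and medium-confidence
#' edges (combined score below `min_score`; an edge at exactly the cutoff is
#' retained), and drops interactions from other species. Edges with a
#' missing taxon are treated as belonging to the requested taxon, for inputs
#' that were pre-restricted upstream.
#'
#' Filtering is idempotent and order-independent.
#'
#' @param edges parsed edge data.frame from [parse_edges()].
#' @param allowed_signs interaction modes to keep. Default
#'   `c("activation", "inhibition")`.
#' @param min_score minimum combined confidence score (kept when
#'   `score >= min_score`). Default 800.
#' @param taxon taxon identifier(s) to keep; human is `"9606"`. Default
#'   `"9606"`.
#' @return the filtered edge data.frame.
#' @export
filter_edges <- function(edges,
                         allowed_signs = c("activation", "inhibition"),
                         min_score = 800, taxon = "9606") {
  if (!is.numeric(min_score) || min_score < 0 || min_score > 1000) {
    stop("'min_score' must be in [0, 1000]")
  }
  keep <- edges$mode %in% allowed_signs &
    edges$score >= min_score &
    (is.na(edges$taxon) | edges$taxon %in% taxon)
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the undirected signed interaction graph
#'
#' Edges are undirected: the underlying interaction evidence carries no
#' reliable direction, so the activation/inhibition sign constrains
#' expression-direction consistency during path search rather than traversal
#' order. The same unordered pair reported with the same sign in both
#' orientations (or repeatedly) collapses to one edge; a pair reported with
#' *both* signs keeps two parallel signed edges, both traversable. Self
#' loops are dropped and counted.
#'
#' @param edges filtered edge data.frame (columns `gene_a`, `gene_b`,
#'   `sign`).
#' @return an object of class `interaction_graph`: list with `edges`
#'   (canonical pair + sign), `adj` (per-node data.frame of
#'   `neighbor`/`sign`), and `nodes`.
#' @export
build_graph <- function(edges) {
  if (nrow(edges) > 0 && any(is.na(edges$sign))) {
    stop("all edges must carry a defined sign; run filter_edges() first")
  }
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  canon <- data.frame(gene_a = a, gene_b = b, sign = edges$sign,
                      stringsAsFactors = FALSE)
  canon <- canon[!duplicated(canon[c("gene_a", "gene_b", "sign")]), ,
                 drop = FALSE]
  rownames(canon) <- NULL

  both <- rbind(
    data.frame(node = canon$gene_a, neighbor = canon$gene_b,
               sign = canon$sign, stringsAsFactors = FALSE),
    data.frame(node = canon$gene_b, neighbor = canon$gene_a,
               sign = canon$sign, stringsAsFactors = FALSE)
  )
  adj <- split(both[c("neighbor", "sign")], both$node)
  nodes <- sort(unique(c(canon$gene_a, canon$gene_b)))
  structure(list(edges = canon, adj = adj, nodes = nodes),
            class = "interaction_graph")
}

#' Signed neighbors of a node
#'
#' @param graph an `interaction_graph`.
#' @param gene node name.
#' @return data.frame with columns `neighbor` and `sign` (zero rows when the
#'   gene is absent or isolated).
#' @export
graph_neighbors <- function(graph, gene) {
  nb <- graph$adj[[gene]]
  if (is.null(nb)) {
    nb <- data.frame(neighbor = character(), sign = character(),
                     stringsAsFactors = FALSE)
  }
  rownames(nb) <- NULL
  nb
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("Signed interaction graph\n")
  cat(sprintf("  %d nodes, %d signed edges (%d activation, %d inhibition)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "activation"),
              sum(x$edges$sign == "inhibition")))
  pairs <- paste(x$edges$gene_a, x$edges$gene_b)
  n_conf <- sum(duplicated(pairs))
  if (n_conf > 0) {
    cat(sprintf("  %d pair(s) carry both signs (kept as parallel edges)\n",
                n_conf))
  }
  invisible(x)
}

#' Export an interaction graph as an edge-list table
#'
#' @param graph an `interaction_graph`.
#' @param path optional path; when given, the edge list is written as TSV.
#' @return the edge data.frame, invisibly when written to a file.
#' @export
graph_edges <- function(graph, path = NULL) {
  edges <- graph$edges
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(edges))
  }
  edges
}
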