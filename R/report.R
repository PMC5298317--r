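#' Count genes in the large and normal methylation-change classes
#'
#' Restricted to genes that are both differentially methylated (present in
#' the gene-level methylation table with FDR below the cutoff) and
#' differentially expressed (expression FDR below the cutoff and
#' `|log2fc| >= log2(fc_threshold)`), counts the genes whose absolute
#' representative methylation change exceeds the large-change `threshold`
#' and those in the normal band (`baseline < |change| <= threshold`).
#'
#' @param gene_meth gene-level methylation table
#'   (from [summarize_methylation()]).
#' @param expression_table expression table (`gene`, `log2fc`, `fdr`).
#' @param threshold large-change threshold (percent). Default 32.2.
#' @param baseline normal-change threshold (percent). Default 15.
#' @param fc_threshold linear fold-change threshold. Default 2.
#' @param fdr_cutoff significance cutoff. Default 0.1.
#' @return named integer vector `c(n_large = ..., n_normal = ...)`.
#' @export
class_counts <- function(gene_meth, expression_table, threshold = 32.2,
                         baseline = 15, fc_threshold = 2, fdr_cutoff = 0.1) {
  if (baseline >= threshold) stop("'baseline' must be below 'threshold'")
  de <- expression_table$gene[
    expression_table$fdr < fdr_cutoff &
      abs(expression_table$log2fc) >= log2(fc_threshold)]
  joint <- gene_meth[gene_meth$fdr < fdr_cutoff &
                       gene_meth$gene %in% de, , drop = FALSE]
  ad <- abs(joint$delta_beta_pct)
  c(n_large = sum(ad > threshold),
    n_normal = sum(ad > baseline & ad <= threshold))
}

#' Genes in the large / normal methylation classes
#'
#' Companion to [class_counts()], returning the gene sets rather than the
#' counts.
#'
#' @inheritParams class_counts
#' @return list with character vectors `large` and `normal`.
#' @export
class_gene_sets <- function(gene_meth, expression_table, threshold = 32.2,
                            baseline = 15, fc_threshold = 2,
                            fdr_cutoff = 0.1) {
  if (baseline >= threshold) stop("'baseline' must be below 'threshold'")
  de <- expression_table$gene[
    expression_table$fdr < fdr_cutoff &
      abs(expression_table$log2fc) >= log2(fc_threshold)]
  joint <- gene_meth[gene_meth$fdr < fdr_cutoff &
                       gene_meth$gene %in% de, , drop = FALSE]
  ad <- abs(joint$delta_beta_pct)
  list(large = joint$gene[ad > threshold],
       normal = joint$gene[ad > baseline & ad <= threshold])
}

#' Cross-cohort shared-driver distance table
#'
#' For each driver gene, its minimal methylation-driven path distance in
#' every cohort (restricted to distances up to `max_distance`); only
#' drivers observed in at least `min_datasets` cohorts are kept. Rows are
#' ordered by the number of cohorts sharing the driver (descending), then
#' by gene symbol.
#'
#' @param per_dataset_paths named list of path data.frames (one per cohort,
#'   as from [search_paths()]).
#' @param min_datasets minimum number of cohorts a driver must appear in.
#'   Default 2.
#' @param max_distance largest distance included. Default 3.
#' @return data.frame with `driver`, one integer column per cohort (NA when
#'   the driver has no qualifying path there), and `n_datasets`.
#' @export
cross_cancer_table <- function(per_dataset_paths, min_datasets = 2,
                               max_distance = 3) {
  datasets <- names(per_dataset_paths)
  if (is.null(datasets) || any(datasets == "")) {
    stop("'per_dataset_paths' must be a named list")
  }
  mins <- lapply(per_dataset_paths, function(p) {
    if (nrow(p) == 0L) return(integer())
    m <- tapply(p$distance, p$driver, min)
    m[m <= max_distance]
  })
  all_drivers <- sort(unique(unlist(lapply(mins, names))))
  if (length(all_drivers) == 0L) {
    out <- data.frame(driver = character(), stringsAsFactors = FALSE)
    for (d in datasets) out[[d]] <- integer()
    out$n_datasets <- integer()
    return(out)
  }
  mat <- sapply(datasets, function(d) {
    as.integer(mins[[d]][all_drivers])
  })
  mat <- matrix(mat, nrow = length(all_drivers),
                dimnames = list(all_drivers, datasets))
  n_ds <- rowSums(!is.na(mat))
  keep <- n_ds >= min_datasets
  mat <- mat[keep, , drop = FALSE]
  n_ds <- n_ds[keep]
  ord <- order(-n_ds, rownames(mat))
  out <- data.frame(driver = rownames(mat)[ord], mat[ord, , drop = FALSE],
                    n_datasets = as.integer(n_ds[ord]),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Cross-cohort averages of close proportions and distances
#'
#' Averages the per-cohort close proportions and average distances of each
#' methylation class. By default each cohort's proportion is first rounded
#' to `digits` decimals before averaging, which matches arithmetic performed
#' on published two-decimal tables; `rounded = FALSE` averages the raw
#' ratios. Cohorts named in `exclude_from_distance` are left out of the
#' distance average only (e.g. an outlier cohort whose distances move
#' against the trend).
#'
#' @param summary_rows data.frame with one row per cohort and class:
#'   columns `dataset`, `meth_class`, `n_close`, `n_with_path`,
#'   `avg_distance`; an optional `close_proportion` column carries
#'   already-printed per-cohort ratios, which take precedence in rounded
#'   mode (published tables occasionally print a ratio that differs in the
#'   last digit from the rounded quotient of the printed counts).
#' @param rounded round each proportion to `digits` decimals before
#'   averaging. Default TRUE.
#' @param digits decimals for the per-cohort proportion. Default 2.
#' @param exclude_from_distance cohorts excluded from the distance average.
#' @return list with `class_summary` (per class: mean close proportion in
#'   percent and mean average distance, each rounded to `digits`),
#'   `proportions` (per cohort and class), and `distance_difference` (per
#'   cohort: large-class minus normal-class average distance).
#' @export
averages_summary <- function(summary_rows, rounded = TRUE, digits = 2,
                             exclude_from_distance = NULL) {
  need <- c("dataset", "meth_class", "n_close", "n_with_path",
            "avg_distance")
  miss <- setdiff(need, names(summary_rows))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  rows <- summary_rows
  rows$proportion <- ifelse(rows$n_with_path > 0,
                            rows$n_close / rows$n_with_path, 0)
  if (rounded) {
    rows$proportion <- if ("close_proportion" %in% names(rows)) {
      round(rows$close_proportion, digits)
    } else {
      round(rows$proportion, digits)
    }
  }

  classes <- unique(rows$meth_class)
  class_summary <- do.call(rbind, lapply(classes, function(cl) {
    sub <- rows[rows$meth_class == cl, , drop = FALSE]
    dsub <- sub[!sub$dataset %in% exclude_from_distance, , drop = FALSE]
    data.frame(
      meth_class = cl,
      mean_close_proportion_pct = round(100 * mean(sub$proportion), digits),
      mean_avg_distance = round(mean(dsub$avg_distance, na.rm = TRUE),
                                digits),
      stringsAsFactors = FALSE
    )
  }))
  rownames(class_summary) <- NULL

  diff_tab <- NULL
  if (all(c("large", "normal") %in% classes)) {
    lg <- rows[rows$meth_class == "large", c("dataset", "avg_distance")]
    nm <- rows[rows$meth_class == "normal", c("dataset", "avg_distance")]
    m <- merge(lg, nm, by = "dataset", suffixes = c("_large", "_normal"))
    diff_tab <- data.frame(
      dataset = m$dataset,
      difference = round(m$avg_distance_large - m$avg_distance_normal,
                         digits),
      stringsAsFactors = FALSE
    )
  }
  list(class_summary = class_summary,
       proportions = rows[c("dataset", "meth_class", "proportion")],
       distance_difference = diff_tab)
}

#' Cross-cohort set-intersection counts
#'
#' UpSet-style breakdown of how affected driver genes are shared across
#' cohorts: every gene in the union is assigned to its exact membership
#' pattern, and genes are counted per observed pattern. Patterns include
#' the single-cohort ("unique") ones; the counts over all patterns sum to
#' the size of the union.
#'
#' @param per_dataset_sets named list of character vectors (gene sets, one
#'   per cohort).
#' @return data.frame with `pattern` (cohort names joined by `"&"`),
#'   `degree` (number of cohorts in the pattern), `count`, and `genes`
#'   (symbols joined by `","`); per-cohort totals in attribute
#'   `set_totals`.
#' @export
intersection_counts <- function(per_dataset_sets) {
  if (length(per_dataset_sets) == 0L) stop("need at least one set")
  ds <- names(per_dataset_sets)
  if (is.null(ds) || any(ds == "")) {
    stop("'per_dataset_sets' must be a named list")
  }
  u <- sort(unique(unlist(per_dataset_sets)))
  if (length(u) == 0L) {
    out <- data.frame(pattern = character(), degree = integer(),
                      count = integer(), genes = character(),
                      stringsAsFactors = FALSE)
    attr(out, "set_totals") <- stats::setNames(integer(length(ds)), ds)
    return(out)
  }
  memb <- vapply(per_dataset_sets, function(s) u %in% s,
                 logical(length(u)))
  memb <- matrix(memb, nrow = length(u), dimnames = list(u, ds))
  pattern <- apply(memb, 1L, function(r) paste(ds[r], collapse = "&"))
  split_genes <- split(u, pattern)
  out <- data.frame(
    pattern = names(split_genes),
    degree = lengths(gregexpr("&", names(split_genes), fixed = TRUE)) + 1L,
    count = lengths(split_genes),
    genes = vapply(split_genes, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  out$degree <- vapply(strsplit(out$pattern, "&", fixed = TRUE), length,
                       integer(1))
  out <- out[order(-out$degree, -out$count, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "set_totals") <- colSums(memb)
  out
}
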