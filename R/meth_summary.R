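#' Remove probes overlapping common polymorphisms
#'
#' Probes whose annotated SNP minor-allele frequency exceeds the cutoff are
#' dropped, because a common polymorphism under the probe can mimic a
#' methylation change. The inequality is strict: a probe at exactly the
#' cutoff is retained. Probes without a MAF annotation (NA) are retained, and
#' a table with no `snp_maf` column is returned unchanged.
#'
#' @param cpg_table data.frame of per-CpG records with at least `cpg_id`,
#'   `gene`, `delta_beta_pct`, `fdr`, optionally `snp_maf`.
#' @param maf_cutoff minor-allele-frequency cutoff in \[0, 1\]. Default 0.05.
#' @return the filtered table; the number of removed rows is attached as
#'   attribute `n_removed`.
#' @export
filter_snp_probes <- function(cpg_table, maf_cutoff = 0.05) {
  if (!is.numeric(maf_cutoff) || length(maf_cutoff) != 1L ||
      maf_cutoff < 0 || maf_cutoff > 1) {
    stop("'maf_cutoff' must be a single value in [0, 1]")
  }
  if (!"snp_maf" %in% names(cpg_table)) {
    attr(cpg_table, "n_removed") <- 0L
    return(cpg_table)
  }
  drop <- !is.na(cpg_table$snp_maf) & cpg_table$snp_maf > maf_cutoff
  out <- cpg_table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  if (any(drop)) {
    message(sum(drop), " probe(s) removed by the SNP MAF filter (> ",
            maf_cutoff, ")")
  }
  out
}

#' General trend of methylation change for one gene
#'
#' A gene commonly carries several differentially methylated CpG regions
#' whose changes disagree in direction. The general trend is the direction of
#' the majority of *significant* changes (FDR below the cutoff; zero changes
#' are uninformative and ignored). An equal split is broken in favor of the
#' direction carrying the larger total absolute change; an exact tie leaves
#' the gene without a trend and it is dropped from the gene-level summary.
#'
#' @param cpg_records data.frame of the CpG records of a single gene
#'   (columns `delta_beta_pct`, `fdr`).
#' @param fdr_cutoff significance cutoff on the probe FDR. Default 0.1.
#' @return `"up"`, `"down"`, or `NA_character_` when no significant probe
#'   exists or the tie cannot be broken (the reason is attached as attribute
#'   `reason`).
#' @export
gene_trend <- function(cpg_records, fdr_cutoff = 0.1) {
  sig <- cpg_records[cpg_records$fdr < fdr_cutoff &
                       cpg_records$delta_beta_pct != 0, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(structure(NA_character_, reason = "no significant probes"))
  }
  n_up <- sum(sig$delta_beta_pct > 0)
  n_down <- sum(sig$delta_beta_pct < 0)
  if (n_up > n_down) return("up")
  if (n_down > n_up) return("down")
  tot_up <- sum(sig$delta_beta_pct[sig$delta_beta_pct > 0])
  tot_down <- sum(abs(sig$delta_beta_pct[sig$delta_beta_pct < 0]))
  if (tot_up > tot_down) return("up")
  if (tot_down > tot_up) return("down")
  structure(NA_character_, reason = "ambiguous trend (exact tie)")
}

#' Representative methylation change for one gene
#'
#' Among a gene's CpG records, the representative is the one with the
#' greatest absolute change among records that are significant (FDR below the
#' cutoff) *and* change in the same direction as the gene's general trend.
#' Ties in absolute change are broken by smaller FDR, then by lexicographic
#' probe id, so the output is deterministic.
#'
#' @param cpg_records data.frame of one gene's CpG records (columns `cpg_id`,
#'   `delta_beta_pct`, `fdr`, optionally `region`, `gene`).
#' @param trend `"up"` or `"down"`, from [gene_trend()].
#' @param fdr_cutoff significance cutoff. Default 0.1.
#' @return a one-row data.frame (`gene`, `delta_beta_pct`, `fdr`, `trend`,
#'   `representative_cpg`, `region`), or `NULL` when no record qualifies.
#' @export
representative_change <- function(cpg_records, trend, fdr_cutoff = 0.1) {
  if (is.na(trend) || !trend %in% c("up", "down")) {
    stop("'trend' must be \"up\" or \"down\"")
  }
  want <- if (trend == "up") 1 else -1
  cand <- cpg_records[cpg_records$fdr < fdr_cutoff &
                        sign(cpg_records$delta_beta_pct) == want, ,
                      drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  ord <- order(-abs(cand$delta_beta_pct), cand$fdr, cand$cpg_id)
  best <- cand[ord[1L], , drop = FALSE]
  data.frame(
    gene = if ("gene" %in% names(best)) best$gene else NA_character_,
    delta_beta_pct = best$delta_beta_pct,
    fdr = best$fdr,
    trend = trend,
    representative_cpg = best$cpg_id,
    region = if ("region" %in% names(best)) best$region else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Collapse per-CpG differential methylation to one change per gene
#'
#' Full gene-level summarization: SNP-overlapping probes are removed
#' ([filter_snp_probes()]), the general trend per gene is determined from the
#' significant probes ([gene_trend()]), and the probe with the greatest
#' absolute significant change in the trend direction becomes the gene's
#' representative methylation change ([representative_change()]). Genes with
#' no significant probe, or with an exactly tied trend, are dropped; the
#' dropped genes and reasons are attached as attribute `dropped`.
#'
#' The output is itself a valid input (the representative probe id doubles as
#' the probe column), so summarization is idempotent.
#'
#' @param cpg_table per-CpG data.frame with columns `cpg_id` (or
#'   `representative_cpg`), `gene`, `delta_beta_pct`, `fdr`; optional
#'   `region` and `snp_maf`.
#' @param maf_cutoff SNP MAF cutoff. Default 0.05.
#' @param fdr_cutoff probe significance cutoff. Default 0.1.
#' @return data.frame with one row per retained gene: `gene`,
#'   `delta_beta_pct`, `fdr`, `trend`, `representative_cpg`, `region`.
#' @examples
#' cpg <- data.frame(
#'   cpg_id = c("cg01", "cg02", "cg03"),
#'   gene = "TP53",
#'   region = c("TSS200", "Body", "TSS1500"),
#'   delta_beta_pct = c(20, 35, -40),
#'   fdr = c(0.01, 0.05, 0.001)
#' )
#' summarize_methylation(cpg)  # trend up, representative +35
#' @export
summarize_methylation <- function(cpg_table, maf_cutoff = 0.05,
                                  fdr_cutoff = 0.1) {
  need <- c("gene", "delta_beta_pct", "fdr")
  miss <- setdiff(need, names(cpg_table))
  if (length(miss) > 0L) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (!"cpg_id" %in% names(cpg_table)) {
    if ("representative_cpg" %in% names(cpg_table)) {
      cpg_table$cpg_id <- cpg_table$representative_cpg
    } else {
      stop("missing required column(s): cpg_id")
    }
  }
  if (!"region" %in% names(cpg_table)) cpg_table$region <- NA_character_

  tab <- filter_snp_probes(cpg_table, maf_cutoff)
  all_genes <- unique(tab$gene)

  sig <- tab[tab$fdr < fdr_cutoff & tab$delta_beta_pct != 0, , drop = FALSE]
  if (nrow(sig) == 0L) {
    out <- data.frame(gene = character(), delta_beta_pct = numeric(),
                      fdr = numeric(), trend = character(),
                      representative_cpg = character(),
                      region = character(), stringsAsFactors = FALSE)
    attr(out, "dropped") <- data.frame(gene = all_genes,
                                       reason = "no significant probes",
                                       stringsAsFactors = FALSE)
    return(out)
  }

  up <- sig$delta_beta_pct > 0
  n_up <- rowsum(as.numeric(up), sig$gene)
  n_down <- rowsum(as.numeric(!up), sig$gene)
  tot_up <- rowsum(ifelse(up, sig$delta_beta_pct, 0), sig$gene)
  tot_down <- rowsum(ifelse(up, 0, -sig$delta_beta_pct), sig$gene)
  genes <- rownames(n_up)
  trend <- ifelse(n_up[, 1] > n_down[, 1], "up",
           ifelse(n_down[, 1] > n_up[, 1], "down",
           ifelse(tot_up[, 1] > tot_down[, 1], "up",
           ifelse(tot_down[, 1] > tot_up[, 1], "down", NA_character_))))
  names(trend) <- genes

  gene_trend_of_row <- trend[sig$gene]
  want <- ifelse(gene_trend_of_row == "up", 1, -1)
  cand <- sig[!is.na(gene_trend_of_row) &
                sign(sig$delta_beta_pct) == want, , drop = FALSE]
  ord <- order(cand$gene, -abs(cand$delta_beta_pct), cand$fdr, cand$cpg_id)
  cand <- cand[ord, , drop = FALSE]
  best <- cand[!duplicated(cand$gene), , drop = FALSE]

  out <- data.frame(
    gene = best$gene,
    delta_beta_pct = best$delta_beta_pct,
    fdr = best$fdr,
    trend = unname(trend[best$gene]),
    representative_cpg = best$cpg_id,
    region = best$region,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL

  dropped_genes <- setdiff(all_genes, out$gene)
  if (length(dropped_genes) > 0L) {
    reason <- ifelse(dropped_genes %in% genes,
                     "ambiguous trend (exact tie)",
                     "no significant probes")
    attr(out, "dropped") <- data.frame(gene = dropped_genes, reason = reason,
                                       stringsAsFactors = FALSE)
    message(length(dropped_genes),
            " gene(s) dropped during gene-level summarization")
  } else {
    attr(out, "dropped") <- data.frame(gene = character(),
                                       reason = character(),
                                       stringsAsFactors = FALSE)
  }
  out
}

#' Benjamini-Hochberg FDR helper
#'
#' Thin convenience wrapper: adds a BH-adjusted `fdr` column computed from a
#' p-value column, for callers whose upstream tables carry raw p-values. The
#' pipeline otherwise consumes FDRs directly.
#'
#' @param table a data.frame.
#' @param p_col name of the p-value column. Default `"pvalue"`.
#' @return the table with an `fdr` column appended (overwritten if present).
#' @export
adjust_fdr <- function(table, p_col = "pvalue") {
  if (!p_col %in% names(table)) stop("no column named '", p_col, "'")
  table$fdr <- stats::p.adjust(table[[p_col]], method = "BH")
  table
}
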