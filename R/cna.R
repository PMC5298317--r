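#' Read a SEG-format copy-number segment file
#'
#' SEG files are tab-separated with one segmented region per row: sample
#' identifier, chromosome, 1-based inclusive start and end, and the
#' segmental mean. Coordinates are converted to 0-based half-open on read,
#' matching the package's internal convention (and BED).
#'
#' @param path path to the SEG/TSV file (header row expected; the usual
#'   `ID`, `chrom`, `loc.start`, `loc.end`, `seg.mean` names or the
#'   equivalents below are recognized).
#' @return data.frame with columns `sample`, `chrom`, `start`, `end`
#'   (0-based half-open), `seg_mean`.
#' @export
read_seg <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  pick <- function(options) {
    hit <- intersect(options, names(raw))
    if (length(hit) == 0L) {
      stop("SEG file lacks a recognized column among: ",
           paste(options, collapse = ", "))
    }
    raw[[hit[1L]]]
  }
  data.frame(
    sample = as.character(pick(c("sample", "ID", "Sample", "sampleID"))),
    chrom = as.character(pick(c("chrom", "chromosome", "Chromosome"))),
    start = as.numeric(pick(c("loc.start", "start", "Start"))) - 1,
    end = as.numeric(pick(c("loc.end", "end", "End"))),
    seg_mean = as.numeric(pick(c("seg.mean", "seg_mean", "Segment_Mean"))),
    stringsAsFactors = FALSE
  )
}

#' Read gene coordinates from a BED file
#'
#' @param path path to a BED file (0-based half-open; the 4th column is the
#'   gene name).
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    gene = if (!is.null(gr$name)) as.character(gr$name)
           else paste0("region_", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Assign per-sample segmental means to genes
#'
#' Overlaps each sample's copy-number segments with whole-gene intervals
#' (the entire gene footprint is used, not individual genomic sub-regions).
#' A gene overlapped by several segments in one sample takes, under the
#' default rule, the segmental mean of the segment with the largest overlap
#' (ties broken by the leftmost segment); `rule = "weighted_mean"` instead
#' averages the overlapping segmental means weighted by overlap length.
#' A gene with no overlapping segment in a sample yields no row (missing,
#' not zero).
#'
#' @param segments segment data.frame (`sample`, `chrom`, `start`, `end`,
#'   `seg_mean`; 0-based half-open, as from [read_seg()]).
#' @param gene_coords gene coordinate data.frame (`gene`, `chrom`, `start`,
#'   `end`; 0-based half-open, as from [read_bed()]).
#' @param rule `"largest_overlap"` (default) or `"weighted_mean"`.
#' @return data.frame with columns `gene`, `sample`, `seg_mean`.
#' @export
map_segments_to_genes <- function(segments, gene_coords,
                                  rule = c("largest_overlap",
                                           "weighted_mean")) {
  rule <- match.arg(rule)
  empty <- data.frame(gene = character(), sample = character(),
                      seg_mean = numeric(), stringsAsFactors = FALSE)
  if (nrow(segments) == 0L || nrow(gene_coords) == 0L) return(empty)
  if (any(segments$start >= segments$end)) {
    stop("segments must satisfy start < end")
  }
  gene_gr <- GenomicRanges::GRanges(
    gene_coords$chrom,
    IRanges::IRanges(start = gene_coords$start + 1L, end = gene_coords$end))
  out <- lapply(split(segments, segments$sample), function(seg) {
    seg_gr <- GenomicRanges::GRanges(
      seg$chrom, IRanges::IRanges(start = seg$start + 1L, end = seg$end))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gene_gr, seg_gr))
    if (length(hits) == 0L) return(NULL)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(gene_gr[qi], seg_gr[si]))
    if (rule == "largest_overlap") {
      ord <- order(qi, -ov, seg$start[si])
      first <- !duplicated(qi[ord])
      data.frame(gene = gene_coords$gene[qi[ord][first]],
                 sample = seg$sample[1L],
                 seg_mean = seg$seg_mean[si[ord][first]],
                 stringsAsFactors = FALSE)
    } else {
      wsum <- rowsum(ov * seg$seg_mean[si], qi)
      wtot <- rowsum(ov, qi)
      idx <- as.integer(rownames(wsum))
      data.frame(gene = gene_coords$gene[idx],
                 sample = seg$sample[1L],
                 seg_mean = wsum[, 1] / wtot[, 1],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Copy-number call for one gene across samples
#'
#' Counts the samples whose segmental mean for the gene reaches
#' `+threshold` or `-threshold` (inclusive) and classifies the gene:
#' `"increased"` / `"decreased"` when only one direction occurs,
#' `"not_important"` when both directions occur across samples of the same
#' dataset (the aberration then cannot consistently explain an expression
#' change), and `"neutral"` when no sample reaches the threshold.
#'
#' @param values numeric vector of per-sample segmental means for one gene
#'   (missing samples omitted, not zero-filled).
#' @param threshold positive segmental-mean threshold. Default 2.
#' @return list with `n_increased`, `n_decreased`, `status`.
#' @examples
#' call_gene_cna(c(2.5, 2.1))$status   # "increased"
#' call_gene_cna(c(2.5, -2.5))$status  # "not_important"
#' call_gene_cna(c(1.0, -0.5))$status  # "neutral"
#' @export
call_gene_cna <- function(values, threshold = 2) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("'threshold' must be positive")
  }
  values <- values[!is.na(values)]
  n_inc <- sum(values >= threshold)
  n_dec <- sum(values <= -threshold)
  status <- if (n_inc > 0L && n_dec > 0L) "not_important"
            else if (n_inc > 0L) "increased"
            else if (n_dec > 0L) "decreased"
            else "neutral"
  list(n_increased = n_inc, n_decreased = n_dec, status = status)
}

#' Copy-number calls for all genes
#'
#' Applies [call_gene_cna()] to every gene of a mapped gene-by-sample
#' segmental-mean table.
#'
#' @param mapped data.frame from [map_segments_to_genes()].
#' @param threshold segmental-mean threshold. Default 2.
#' @param genes optional gene subset (e.g. the driver genes of interest).
#' @return data.frame with columns `gene`, `n_increased`, `n_decreased`,
#'   `status`.
#' @export
cna_calls <- function(mapped, threshold = 2, genes = NULL) {
  if (!is.null(genes)) {
    mapped <- mapped[mapped$gene %in% genes, , drop = FALSE]
  }
  if (nrow(mapped) == 0L) {
    return(data.frame(gene = character(), n_increased = integer(),
                      n_decreased = integer(), status = character(),
                      stringsAsFactors = FALSE))
  }
  calls <- lapply(split(mapped$seg_mean, mapped$gene), call_gene_cna,
                  threshold = threshold)
  out <- data.frame(
    gene = names(calls),
    n_increased = vapply(calls, `[[`, integer(1), "n_increased"),
    n_decreased = vapply(calls, `[[`, integer(1), "n_decreased"),
    status = vapply(calls, `[[`, character(1), "status"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
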