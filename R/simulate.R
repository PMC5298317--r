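#' Configuration for the synthetic cohort generator
#'
#' Collects, with validation, every setting of the synthetic data generator:
#' the size of the gene universe, the Cauchy parameters of the pooled
#' representative methylation changes (the generator's defaults are the
#' pooled-cohort estimates, center 16.8% and scale 7.77%), the fraction of
#' genes with significant methylation, the driver catalog, the
#' sign-consistent cascades planted into the interaction network at known
#' distances, the number of random background edges, and per-gene
#' copy-number profiles.
#'
#' @param n_genes number of background genes. Default 2000.
#' @param n_cpgs_per_gene length-2 integer range of CpG probes per gene.
#'   Default `c(1, 6)`.
#' @param cauchy_center Cauchy location of the representative methylation
#'   changes, in percent. Default 16.8.
#' @param cauchy_scale Cauchy scale in percent (> 0). Default 7.77.
#' @param frac_significant fraction of background genes whose probes reach
#'   methylation significance. Default 0.8.
#' @param frac_snp_probes fraction of background genes receiving an extra
#'   decoy probe overlapping a common SNP (MAF > 0.05). Default 0.02.
#' @param drivers data.frame (`gene`, `role`) of catalog drivers; when NULL
#'   a default catalog of `n_drivers` genes with alternating roles is
#'   created.
#' @param n_drivers size of the default driver catalog. Default 4.
#' @param planted_cascades list of cascades, each a list with `driver`
#'   (catalog gene), `distance` (0..7) and `signs` (character vector of
#'   `distance` activation/inhibition edge signs).
#' @param background_edge_count random interaction edges among background
#'   genes. Default 300.
#' @param large_threshold large methylation change threshold in percent
#'   used when planting terminals. Default 32.2.
#' @param baseline_threshold baseline threshold in percent. Default 15.
#' @param cna_profiles named list: gene -> numeric vector of per-sample
#'   segmental means to emit for that gene.
#' @return validated object of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_cpgs_per_gene = c(1L, 6L),
                              cauchy_center = 16.8,
                              cauchy_scale = 7.77,
                              frac_significant = 0.8,
                              frac_snp_probes = 0.02,
                              drivers = NULL,
                              n_drivers = 4,
                              planted_cascades = list(),
                              background_edge_count = 300,
                              large_threshold = 32.2,
                              baseline_threshold = 15,
                              cna_profiles = list()) {
  chk_count <- function(x, name, min = 0) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != floor(x)) {
      stop("invalid field '", name, "': must be an integer >= ", min)
    }
  }
  chk_frac <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("invalid field '", name, "': must be in [0, 1]")
    }
  }
  chk_count(n_genes, "n_genes", min = 1)
  if (length(n_cpgs_per_gene) != 2L || any(n_cpgs_per_gene < 1) ||
      n_cpgs_per_gene[1] > n_cpgs_per_gene[2]) {
    stop("invalid field 'n_cpgs_per_gene': must be an increasing pair >= 1")
  }
  if (!is.numeric(cauchy_center) || !is.finite(cauchy_center)) {
    stop("invalid field 'cauchy_center': must be finite")
  }
  if (!is.numeric(cauchy_scale) || cauchy_scale <= 0) {
    stop("invalid field 'cauchy_scale': must be > 0")
  }
  chk_frac(frac_significant, "frac_significant")
  chk_frac(frac_snp_probes, "frac_snp_probes")
  chk_count(background_edge_count, "background_edge_count")
  if (baseline_threshold <= 0 || large_threshold <= baseline_threshold) {
    stop("invalid field 'large_threshold': need ",
         "0 < baseline_threshold < large_threshold")
  }
  if (is.null(drivers)) {
    chk_count(n_drivers, "n_drivers", min = 0)
    drivers <- if (n_drivers > 0) {
      data.frame(gene = sprintf("DRV%02d", seq_len(n_drivers)),
                 role = rep_len(c("oncogene", "suppressor"), n_drivers),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = character(), role = character(),
                 stringsAsFactors = FALSE)
    }
  }
  if (!all(c("gene", "role") %in% names(drivers)) ||
      !all(drivers$role %in% c("oncogene", "suppressor"))) {
    stop("invalid field 'drivers': needs 'gene' and 'role' ",
         "(oncogene/suppressor) columns")
  }
  for (i in seq_along(planted_cascades)) {
    cs <- planted_cascades[[i]]
    if (is.null(cs$driver) || !cs$driver %in% drivers$gene) {
      stop("invalid field 'planted_cascades': cascade ", i,
           " driver not in the driver catalog")
    }
    if (is.null(cs$distance) || cs$distance < 0 || cs$distance > 7 ||
        cs$distance != floor(cs$distance)) {
      stop("invalid field 'planted_cascades': cascade ", i,
           " distance must be an integer in 0..7")
    }
    signs <- if (is.null(cs$signs)) character() else cs$signs
    if (length(signs) != cs$distance ||
        !all(signs %in% c("activation", "inhibition"))) {
      stop("invalid field 'planted_cascades': cascade ", i,
           " needs 'distance' activation/inhibition edge signs")
    }
  }
  if (length(cna_profiles) > 0 &&
      (is.null(names(cna_profiles)) || any(names(cna_profiles) == ""))) {
    stop("invalid field 'cna_profiles': must be a named list")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_cpgs_per_gene = as.integer(n_cpgs_per_gene),
         cauchy_center = cauchy_center,
         cauchy_scale = cauchy_scale,
         frac_significant = frac_significant,
         frac_snp_probes = frac_snp_probes,
         drivers = drivers,
         planted_cascades = planted_cascades,
         background_edge_count = as.integer(background_edge_count),
         large_threshold = large_threshold,
         baseline_threshold = baseline_threshold,
         cna_profiles = cna_profiles),
    class = "sim_config"
  )
}

# Resolve the planted cascades into concrete nodes, edges and required
# expression directions. Deterministic (no randomness): cascade node names
# are derived from the cascade index; the activation/inhibition algebra
# propagates the driver's expression direction along the chain (activation
# preserves it, inhibition flips it).
.cascade_plan <- function(config) {
  flip <- function(d) ifelse(d == "up", "down", "up")
  role_dir <- stats::setNames(
    ifelse(config$drivers$role == "oncogene", "up", "down"),
    config$drivers$gene)
  directions <- role_dir
  nodes <- list()
  edges <- list()
  paths <- list()
  for (i in seq_along(config$planted_cascades)) {
    cs <- config$planted_cascades[[i]]
    d <- cs$distance
    chain <- if (d == 0) {
      cs$driver
    } else {
      c(cs$driver,
        if (d > 1) sprintf("C%02dM%d", i, seq_len(d - 1)) else character(),
        sprintf("C%02dT", i))
    }
    dir <- role_dir[[cs$driver]]
    dirs <- dir
    for (s in cs$signs) {
      dir <- if (s == "activation") dir else flip(dir)
      dirs <- c(dirs, dir)
    }
    directions[chain] <- dirs
    kind <- c("driver",
              if (d > 1) rep("intermediate", d - 1) else character(),
              if (d > 0) "terminal" else character())
    if (d == 0) kind <- "terminal"
    nodes[[i]] <- data.frame(gene = chain, cascade = i, kind = kind,
                             direction = dirs, stringsAsFactors = FALSE)
    if (d > 0) {
      edges[[i]] <- data.frame(from = chain[-length(chain)],
                               to = chain[-1], sign = cs$signs,
                               cascade = i, stringsAsFactors = FALSE)
    }
    paths[[i]] <- data.frame(driver = cs$driver,
                             terminal = chain[length(chain)],
                             distance = as.integer(d),
                             nodes = paste(chain, collapse = "_"),
                             signs = paste(cs$signs, collapse = "_"),
                             stringsAsFactors = FALSE)
  }
  node_tab <- if (length(nodes) > 0) do.call(rbind, nodes) else
    data.frame(gene = character(), cascade = integer(), kind = character(),
               direction = character(), stringsAsFactors = FALSE)
  edge_tab <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), sign = character(),
               cascade = integer(), stringsAsFactors = FALSE)
  path_tab <- if (length(paths) > 0) do.call(rbind, paths) else
    data.frame(driver = character(), terminal = character(),
               distance = integer(), nodes = character(),
               signs = character(), stringsAsFactors = FALSE)
  list(nodes = node_tab, edges = edge_tab, paths = path_tab,
       directions = directions)
}

#' Simulate a per-CpG differential methylation table
#'
#' Background genes receive a representative methylation change drawn from a
#' Cauchy distribution with the configured center and scale, truncated to
#' \[-100, 100\] percent by redrawing. Each gene carries one representative
#' probe plus a random number of secondary probes constructed so that the
#' gene-level summarization rules recover the representative exactly:
#' secondary probes in the trend direction are significant with smaller
#' absolute changes, and counter-trend probes are never significant.
#' Genes designated non-significant get only probes with FDR at or above
#' 0.1. A configurable fraction of genes receives an extra decoy probe
#' annotated with a common SNP (MAF > 0.05) and a spuriously large change,
#' which the SNP filter must remove. Cascade genes are forced to the
#' methylation levels their planted role requires: terminals get a change
#' beyond the large threshold with sign opposite their required expression
#' direction; drivers and intermediates stay well below the baseline
#' threshold.
#'
#' @param config a `sim_config`.
#' @param seed integer seed; identical (config, seed) pairs give identical
#'   tables.
#' @return list with `cpg` (columns `cpg_id`, `gene`, `region`,
#'   `delta_beta_pct`, `fdr`, `snp_maf`) and `truth` (per-gene: `gene`,
#'   `delta_beta_pct`, `trend`, `significant`, `kind`, `expr_direction`).
#' @export
simulate_methylation <- function(config, seed = 1) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  set.seed(seed)
  regions <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR",
               "IGR")
  plan <- .cascade_plan(config)

  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  d <- rtrunc_cauchy(n, config$cauchy_center, config$cauchy_scale)
  sig <- stats::runif(n) < config$frac_significant

  rep_probe <- data.frame(
    cpg_id = paste0(genes, "_cg01"),
    gene = genes,
    region = sample(regions, n, replace = TRUE),
    delta_beta_pct = d,
    fdr = ifelse(sig, stats::runif(n, 0, 0.099), stats::runif(n, 0.1, 1)),
    snp_maf = NA_real_,
    stringsAsFactors = FALSE
  )

  extra_n <- sample(seq(config$n_cpgs_per_gene[1],
                        config$n_cpgs_per_gene[2]), n, replace = TRUE) - 1L
  idx <- rep(seq_len(n), extra_n)
  m <- length(idx)
  extra <- NULL
  if (m > 0) {
    same <- stats::runif(m) < 0.75
    mag <- abs(d[idx]) * stats::runif(m, 0.2, 0.9)
    delta <- ifelse(same, sign(d[idx]), -sign(d[idx])) * mag
    # counter-trend probes never reach significance, so the majority rule
    # and the argmax rule recover the representative probe exactly
    fdr <- ifelse(sig[idx] & same & stats::runif(m) < 0.6,
                  stats::runif(m, 0, 0.099),
                  stats::runif(m, 0.1, 1))
    extra <- data.frame(
      cpg_id = sprintf("%s_cg%02d", genes[idx],
                       sequence(extra_n[extra_n > 0]) + 1L),
      gene = genes[idx],
      region = sample(regions, m, replace = TRUE),
      delta_beta_pct = delta,
      fdr = fdr,
      snp_maf = NA_real_,
      stringsAsFactors = FALSE
    )
  }

  n_snp <- round(config$frac_snp_probes * n)
  snp <- NULL
  if (n_snp > 0) {
    si <- sample.int(n, n_snp)
    snp <- data.frame(
      cpg_id = paste0(genes[si], "_cgSNP"),
      gene = genes[si],
      region = sample(regions, n_snp, replace = TRUE),
      delta_beta_pct = sample(c(-1, 1), n_snp, TRUE) *
        stats::runif(n_snp, 45, 95),
      fdr = stats::runif(n_snp, 0, 0.05),
      snp_maf = stats::runif(n_snp, 0.06, 0.5),
      stringsAsFactors = FALSE
    )
  }

  special_genes <- unique(c(config$drivers$gene, plan$nodes$gene))
  special <- NULL
  if (length(special_genes) > 0) {
    kind <- rep("driver", length(special_genes))
    names(kind) <- special_genes
    pk <- plan$nodes$kind
    names(pk) <- plan$nodes$gene
    kind[names(pk)] <- pk
    sdelta <- numeric(length(special_genes))
    for (j in seq_along(special_genes)) {
      g <- special_genes[j]
      if (kind[[g]] == "terminal") {
        dir <- plan$directions[[g]]
        mag <- stats::runif(1, config$large_threshold + 3,
                            min(95, config$large_threshold + 45))
        sdelta[j] <- if (dir == "up") -mag else mag
      } else {
        sdelta[j] <- sample(c(-1, 1), 1) *
          stats::runif(1, 1, 0.6 * config$baseline_threshold)
      }
    }
    special <- data.frame(
      cpg_id = paste0(special_genes, "_cg01"),
      gene = special_genes,
      region = sample(regions, length(special_genes), replace = TRUE),
      delta_beta_pct = sdelta,
      fdr = stats::runif(length(special_genes), 0, 0.099),
      snp_maf = NA_real_,
      stringsAsFactors = FALSE
    )
  }

  cpg <- rbind(rep_probe, extra, snp, special)
  cpg <- cpg[order(cpg$gene, cpg$cpg_id), , drop = FALSE]
  rownames(cpg) <- NULL

  truth_bg <- data.frame(
    gene = genes, delta_beta_pct = d,
    trend = ifelse(d > 0, "up", "down"),
    significant = sig, kind = "background",
    expr_direction = NA_character_, stringsAsFactors = FALSE
  )
  truth_sp <- NULL
  if (length(special_genes) > 0) {
    truth_sp <- data.frame(
      gene = special$gene, delta_beta_pct = special$delta_beta_pct,
      trend = ifelse(special$delta_beta_pct > 0, "up", "down"),
      significant = TRUE,
      kind = unname(kind[special$gene]),
      expr_direction = unname(plan$directions[special$gene]),
      stringsAsFactors = FALSE
    )
  }
  truth <- rbind(truth_bg, truth_sp)
  rownames(truth) <- NULL
  list(cpg = cpg, truth = truth)
}

#' Simulate a per-gene differential expression table
#'
#' Genes with a pinned expression direction (cascade drivers, intermediates
#' and terminals of the coupling manifest) receive a significant log2
#' fold-change of magnitude at least 1.2 in that direction. Other
#' methylation-driven genes of the coupling receive a significant change of
#' magnitude at least 1 with sign opposite their methylation change (the
#' inverse methylation/expression relationship). All remaining genes get
#' symmetric zero-centered noise (normal with standard deviation 0.6) and a
#' uniform FDR, so they are independent of their methylation changes.
#'
#' @param gene_truth per-gene truth table from [simulate_methylation()].
#' @param coupling NULL (no methylation/expression coupling), or a list
#'   with `directions` (named `"up"`/`"down"` vector) and `driven_genes`
#'   (character); see [manifest_coupling()]. Unknown genes raise an error.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `log2fc`, `fdr`.
#' @export
simulate_expression <- function(gene_truth, coupling = NULL, seed = 1) {
  set.seed(seed)
  genes <- gene_truth$gene
  n <- length(genes)
  log2fc <- stats::rnorm(n, 0, 0.6)
  fdr <- stats::runif(n, 0, 1)
  if (!is.null(coupling)) {
    dirs <- coupling$directions
    driven <- coupling$driven_genes
    unknown <- setdiff(union(names(dirs), driven), genes)
    if (length(unknown) > 0) {
      stop("coupling names unknown gene(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    di <- match(names(dirs), genes)
    log2fc[di] <- ifelse(dirs == "up", 1, -1) *
      stats::runif(length(di), 1.2, 3.2)
    fdr[di] <- stats::runif(length(di), 0, 0.099)
    rest <- setdiff(driven, names(dirs))
    if (length(rest) > 0) {
      ri <- match(rest, genes)
      log2fc[ri] <- -sign(gene_truth$delta_beta_pct[ri]) *
        stats::runif(length(ri), 1, 3)
      fdr[ri] <- stats::runif(length(ri), 0, 0.099)
    }
  }
  data.frame(gene = genes, log2fc = log2fc, fdr = fdr,
             stringsAsFactors = FALSE)
}

#' Simulate the signed interaction network with planted cascades
#'
#' Emits the planted cascade chains (edge signs exactly as configured, all
#' scores at least 800, human taxon) plus random background
#' activation/inhibition edges among background genes only. Background
#' edges never touch cascade nodes or drivers, so each planted distance is
#' also the true shortest constraint-satisfying distance, and the
#' ground-truth manifest is exact.
#'
#' @param config a `sim_config`.
#' @param gene_truth per-gene truth table from [simulate_methylation()].
#' @param seed integer seed.
#' @return list with `edges` (columns `gene_a`, `gene_b`, `mode`, `score`,
#'   `taxon`, `is_directional`) and `manifest` (class
#'   `ground_truth_manifest`: `planted_paths`, `methylation_driven_genes`,
#'   `driver_direction`, `node_directions`).
#' @export
simulate_network <- function(config, gene_truth, seed = 1) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  set.seed(seed)
  plan <- .cascade_plan(config)
  if (nrow(plan$paths) > 0 && any(plan$paths$distance > 7)) {
    stop("planted cascade distance above 7 is not allowed")
  }
  planted <- if (nrow(plan$edges) > 0) {
    data.frame(gene_a = plan$edges$from, gene_b = plan$edges$to,
               mode = plan$edges$sign,
               score = sample(800:1000, nrow(plan$edges), replace = TRUE),
               taxon = "9606", is_directional = "f",
               stringsAsFactors = FALSE)
  } else {
    NULL
  }
  background <- NULL
  pool <- gene_truth$gene[gene_truth$kind == "background"]
  k <- config$background_edge_count
  if (k > 0 && length(pool) >= 2) {
    a <- sample(pool, 3 * k, replace = TRUE)
    b <- sample(pool, 3 * k, replace = TRUE)
    ok <- a != b
    key <- paste(pmin(a, b), pmax(a, b))
    ok <- ok & !duplicated(key)
    a <- a[ok][seq_len(min(k, sum(ok)))]
    b <- b[ok][seq_len(min(k, sum(ok)))]
    background <- data.frame(
      gene_a = a, gene_b = b,
      mode = sample(c("activation", "inhibition"), length(a),
                    replace = TRUE),
      score = sample(800:1000, length(a), replace = TRUE),
      taxon = "9606", is_directional = "f", stringsAsFactors = FALSE)
  }
  edges <- rbind(planted, background)
  if (is.null(edges)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        mode = character(), score = integer(),
                        taxon = character(), is_directional = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  manifest <- structure(
    list(planted_paths = plan$paths,
         methylation_driven_genes = unique(plan$paths$terminal),
         driver_direction = stats::setNames(
           ifelse(config$drivers$role == "oncogene", "up", "down"),
           config$drivers$gene),
         node_directions = plan$directions),
    class = "ground_truth_manifest")
  list(edges = edges, manifest = manifest)
}

#' Expression coupling specification from a ground-truth manifest
#'
#' @param manifest a `ground_truth_manifest` from [simulate_network()].
#' @return list with `directions` and `driven_genes`, suitable as the
#'   `coupling` argument of [simulate_expression()].
#' @export
manifest_coupling <- function(manifest) {
  list(directions = manifest$node_directions,
       driven_genes = manifest$methylation_driven_genes)
}

#' Deterministic gene coordinates for the simulated universe
#'
#' Tiles the simulated genes across five chromosomes: 10 kb genes every
#' 20 kb, in BED convention (0-based half-open). Purely positional
#' bookkeeping so that copy-number segments can be intersected with genes.
#'
#' @param gene_truth per-gene truth table from [simulate_methylation()].
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
simulate_gene_coords <- function(gene_truth) {
  genes <- gene_truth$gene
  n <- length(genes)
  chrom <- paste0("chr", ((seq_len(n) - 1L) %% 5L) + 1L)
  slot <- (seq_len(n) - 1L) %/% 5L
  data.frame(gene = genes, chrom = chrom,
             start = slot * 20000L, end = slot * 20000L + 10000L,
             stringsAsFactors = FALSE)
}

#' Simulate SEG-format copy-number segments
#'
#' Emits one segment per configured (gene, sample) pair covering the gene
#' with the configured segmental mean, with random padding into the
#' intergenic gaps. Samples are named `S01`, `S02`, ...: a gene whose
#' profile has `k` values aberrates in the first `k` samples. Overlapping
#' segments within one sample are rejected. An empty profile list yields an
#' empty table.
#'
#' @param config a `sim_config` (field `cna_profiles`).
#' @param gene_coords gene coordinates (see [simulate_gene_coords()]).
#' @param seed integer seed.
#' @return SEG-style data.frame: `sample`, `chrom`, `loc.start`, `loc.end`
#'   (1-based inclusive), `seg.mean`.
#' @export
simulate_cna_segments <- function(config, gene_coords, seed = 1) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  set.seed(seed)
  profiles <- config$cna_profiles
  empty <- data.frame(sample = character(), chrom = character(),
                      loc.start = integer(), loc.end = integer(),
                      seg.mean = numeric(), stringsAsFactors = FALSE)
  if (length(profiles) == 0L) return(empty)
  missing <- setdiff(names(profiles), gene_coords$gene)
  if (length(missing) > 0) {
    stop("cna profile gene(s) without coordinates: ",
         paste(missing, collapse = ", "))
  }
  rows <- list()
  for (g in names(profiles)) {
    gc <- gene_coords[gene_coords$gene == g, ]
    v <- profiles[[g]]
    for (j in seq_along(v)) {
      pad_l <- floor(stats::runif(1, 0, 4000))
      pad_r <- floor(stats::runif(1, 0, 4000))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("S%02d", j), chrom = gc$chrom,
        loc.start = gc$start - pad_l + 1L, loc.end = gc$end + pad_r,
        seg.mean = v[j], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$loc.start <- pmax(out$loc.start, 1L)
  for (s in unique(out$sample)) {
    sub <- out[out$sample == s, ]
    sub <- sub[order(sub$chrom, sub$loc.start), ]
    same <- sub$chrom[-1] == sub$chrom[-nrow(sub)]
    if (nrow(sub) > 1 && any(same & sub$loc.start[-1] <= sub$loc.end[-nrow(sub)])) {
      stop("overlapping segments within sample '", s, "'")
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates the four generators with sub-seeds derived from one master
#' seed: methylation (seed), network (seed + 1), expression coupled to the
#' manifest (seed + 2), and copy-number segments (seed + 3), plus the
#' deterministic gene coordinates. Identical (config, seed) pairs give
#' byte-identical outputs.
#'
#' @param config a `sim_config`.
#' @param seed integer master seed.
#' @return list with `cpg`, `truth`, `edges`, `manifest`, `expression`,
#'   `gene_coords`, `segments`, `config`, `seed`.
#' @export
simulate_dataset <- function(config, seed = 1) {
  meth <- simulate_methylation(config, seed)
  net <- simulate_network(config, meth$truth, seed + 1L)
  expr <- simulate_expression(meth$truth, manifest_coupling(net$manifest),
                              seed + 2L)
  coords <- simulate_gene_coords(meth$truth)
  segs <- simulate_cna_segments(config, coords, seed + 3L)
  list(cpg = meth$cpg, truth = meth$truth, edges = net$edges,
       manifest = net$manifest, expression = expr, gene_coords = coords,
       segments = segs, config = config, seed = seed)
}

#' Write a simulated cohort to disk
#'
#' Writes the CpG, expression, edge and truth tables as TSV, gene
#' coordinates as BED (0-based half-open), segments as SEG, and the planted
#' path manifest as a flat TSV.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(
    w(sim$cpg, "methylation_cpg.tsv"),
    w(sim$expression, "expression.tsv"),
    w(sim$edges, "ppi_actions.tsv"),
    w(sim$truth, "gene_truth.tsv"),
    w(sim$segments, "copy_number.seg"),
    w(sim$manifest$planted_paths, "manifest_paths.tsv")
  )
  bed <- sim$gene_coords
  bed_path <- file.path(dir, "gene_coords.bed")
  utils::write.table(bed[c("chrom", "start", "end", "gene")], bed_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(files, bed_path))
}
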