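# Synthetic cohort generator: determinism, distributions, manifests.

test_that("configuration rejects invalid fields with named messages", {
  expect_error(simulation_config(n_genes = -1), "n_genes")
  expect_error(simulation_config(cauchy_scale = 0), "cauchy_scale")
  expect_error(simulation_config(frac_significant = 1.5),
               "frac_significant")
  expect_error(simulation_config(n_cpgs_per_gene = c(3, 1)),
               "n_cpgs_per_gene")
  expect_error(
    simulation_config(planted_cascades = list(
      list(driver = "NOPE", distance = 1, signs = "activation"))),
    "planted_cascades")
  expect_error(
    simulation_config(planted_cascades = list(
      list(driver = "DRV01", distance = 8,
           signs = rep("activation", 8)))),
    "distance")
  expect_error(
    simulation_config(planted_cascades = list(
      list(driver = "DRV01", distance = 2, signs = "activation"))),
    "signs")
})

test_that("identical config and seed give identical outputs", {
  set.seed(1)
  cfg <- cascade_config(c(1, 3))
  s1 <- simulate_dataset(cfg, seed = 7)
  set.seed(99)  # must not matter
  s2 <- simulate_dataset(cfg, seed = 7)
  expect_identical(s1$cpg, s2$cpg)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$segments, s2$segments)
  s3 <- simulate_dataset(cfg, seed = 8)
  expect_false(identical(s1$cpg, s3$cpg))
})

test_that("representative changes follow the configured truncated Cauchy", {
  cfg <- simulation_config(n_genes = 10000, cauchy_center = 0,
                           cauchy_scale = 1, n_drivers = 0,
                           background_edge_count = 0)
  m <- simulate_methylation(cfg, seed = 3)
  # the location estimator applied to the generator's own output
  expect_lt(abs(truncated_mean_center(m$truth$delta_beta_pct)), 0.2)

  # tail mass beyond the published threshold matches the closed-form CDF
  cfg2 <- simulation_config(n_genes = 20000, cauchy_center = 16.8,
                            cauchy_scale = 7.77, n_drivers = 0,
                            background_edge_count = 0)
  m2 <- simulate_methylation(cfg2, seed = 4)
  d <- m2$truth$delta_beta_pct
  p_in <- pcauchy(100, 16.8, 7.77) - pcauchy(-100, 16.8, 7.77)
  p_tail <- (pcauchy(-32.2, 16.8, 7.77) - pcauchy(-100, 16.8, 7.77) +
               pcauchy(100, 16.8, 7.77) - pcauchy(32.2, 16.8, 7.77)) / p_in
  got <- mean(abs(d) > 32.2)
  expect_lt(abs(got - p_tail), 4 * sqrt(p_tail * (1 - p_tail) / length(d)))
})

test_that("emitted changes pass a Kolmogorov-Smirnov check at n = 1e5", {
  cfg <- simulation_config(n_genes = 100000, cauchy_center = 0,
                           cauchy_scale = 1, n_drivers = 0,
                           background_edge_count = 0)
  m <- simulate_methylation(cfg, seed = 5)
  ks <- suppressWarnings(
    ks.test(m$truth$delta_beta_pct, pcauchy, 0, 1))$statistic
  expect_lt(unname(ks), 0.02)
})

test_that("gene-level summarization recovers the generator's truth exactly", {
  cfg <- simulation_config(n_genes = 400, n_drivers = 0,
                           background_edge_count = 0,
                           frac_snp_probes = 0.1)
  m <- simulate_methylation(cfg, seed = 6)
  gm <- suppressMessages(summarize_methylation(m$cpg))
  truth_sig <- m$truth[m$truth$significant, ]
  expect_setequal(gm$gene, truth_sig$gene)
  idx <- match(gm$gene, truth_sig$gene)
  expect_equal(gm$delta_beta_pct, truth_sig$delta_beta_pct[idx])
  expect_identical(gm$trend, truth_sig$trend[idx])
})

test_that("expression coupling is inverse for driven genes, absent otherwise", {
  set.seed(2)
  cfg <- cascade_config(c(2, 4), n_genes = 4000)
  m <- simulate_methylation(cfg, seed = 11)
  net <- simulate_network(cfg, m$truth, seed = 12)
  expr <- simulate_expression(m$truth, manifest_coupling(net$manifest),
                              seed = 13)
  driven <- net$manifest$methylation_driven_genes
  di <- match(driven, expr$gene)
  ti <- match(driven, m$truth$gene)
  expect_true(all(sign(expr$log2fc[di]) ==
                    -sign(m$truth$delta_beta_pct[ti])))
  expect_true(all(abs(expr$log2fc[di]) >= 1))
  expect_true(all(expr$fdr[di] < 0.1))

  # no coupling: methylation and expression signs agree about half the time
  noise <- simulate_expression(m$truth, coupling = NULL, seed = 14)
  agree <- mean(sign(noise$log2fc) == sign(m$truth$delta_beta_pct))
  expect_lt(abs(agree - 0.5), 0.05)

  expect_error(
    simulate_expression(m$truth,
                        coupling = list(directions = c(GHOST = "up"),
                                        driven_genes = character())),
    "unknown")
})

test_that("planted cascades are sound: manifest paths exist with stated signs", {
  skip_if_not_installed("igraph")
  set.seed(3)
  cfg <- cascade_config(c(0, 1, 2, 5), n_genes = 300)
  sim <- simulate_dataset(cfg, seed = 21)
  man <- sim$manifest
  edge_key <- paste(pmin(sim$edges$gene_a, sim$edges$gene_b),
                    pmax(sim$edges$gene_a, sim$edges$gene_b),
                    sim$edges$mode)
  for (i in seq_len(nrow(man$planted_paths))) {
    chain <- strsplit(man$planted_paths$nodes[i], "_", fixed = TRUE)[[1]]
    signs <- if (man$planted_paths$signs[i] == "") character() else
      strsplit(man$planted_paths$signs[i], "_", fixed = TRUE)[[1]]
    expect_equal(length(chain) - 1, man$planted_paths$distance[i])
    if (length(chain) > 1) {
      for (k in seq_len(length(chain) - 1)) {
        expect_true(paste(pmin(chain[k], chain[k + 1]),
                          pmax(chain[k], chain[k + 1]),
                          signs[k]) %in% edge_key,
                    info = paste("cascade", i, "edge", k))
      }
    }
  }
  # brute-force shortest distance on the emitted table equals the manifest
  simple <- unique(sim$edges[c("gene_a", "gene_b")])
  g <- igraph::graph_from_data_frame(simple, directed = FALSE)
  for (i in seq_len(nrow(man$planted_paths))) {
    d <- man$planted_paths$distance[i]
    if (d == 0) next
    got <- igraph::distances(g, man$planted_paths$driver[i],
                             man$planted_paths$terminal[i])
    expect_equal(unname(got[1, 1]), d)
  }
})

test_that("zero background edges leave exactly the cascade edges", {
  cfg <- simulation_config(
    n_genes = 50, background_edge_count = 0,
    planted_cascades = list(list(driver = "DRV01", distance = 3,
                                 signs = rep("activation", 3))))
  sim <- simulate_dataset(cfg, seed = 31)
  expect_equal(nrow(sim$edges), 3)
  expect_true(all(sim$edges$score >= 800))
  expect_true(all(sim$edges$taxon == "9606"))
})

test_that("simulated segments honor the configured per-gene profiles", {
  cfg <- simulation_config(
    n_genes = 60,
    cna_profiles = list(G00007 = c(2.5, 2.1), G00020 = c(2.5, -2.5)))
  m <- simulate_methylation(cfg, seed = 41)
  coords <- simulate_gene_coords(m$truth)
  segs <- simulate_cna_segments(cfg, coords, seed = 42)
  expect_equal(nrow(segs), 4)
  expect_true(all(segs$loc.start >= 1))

  empty_cfg <- simulation_config(n_genes = 10)
  expect_equal(nrow(simulate_cna_segments(empty_cfg, coords, 1)), 0)
})

test_that("written simulation files are plain-text and re-readable", {
  dir <- withr::local_tempdir()
  set.seed(4)
  cfg <- cascade_config(c(1, 2), n_genes = 80,
                        background_edge_count = 20)
  cfg$cna_profiles <- list(G00001 = c(2.5))
  sim <- simulate_dataset(cfg, seed = 51)
  files <- write_simulation(sim, dir)
  expect_true(all(file.exists(files)))
  cpg <- read.delim(file.path(dir, "methylation_cpg.tsv"))
  expect_equal(nrow(cpg), nrow(sim$cpg))
  seg <- read_seg(file.path(dir, "copy_number.seg"))
  expect_equal(seg$start, sim$segments$loc.start - 1)
  bed <- read_bed(file.path(dir, "gene_coords.bed"))
  expect_setequal(bed$gene, sim$gene_coords$gene)
  expect_equal(bed$start[match(sim$gene_coords$gene, bed$gene)],
               sim$gene_coords$start)
})
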