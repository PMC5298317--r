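# Driver annotation and the sign-consistent breadth-first path search.

test_that("driver annotation needs the role-concordant significant change", {
  expr <- make_expr(c("ONC1", "SUP1", "ONC2", "SUP2"),
                    c(2.5, 3.0, 0.5, -2.0))
  catalog <- data.frame(
    gene = c("ONC1", "SUP1", "ONC2", "SUP2", "GHOST"),
    role = c("oncogene", "suppressor", "oncogene", "suppressor",
             "oncogene"),
    stringsAsFactors = FALSE)
  out <- suppressMessages(annotate_drivers(expr, catalog))
  expect_equal(attr(out, "n_missing"), 1L)
  got <- setNames(out$dysregulated, out$gene)
  expect_true(got[["ONC1"]])    # up oncogene
  expect_false(got[["SUP1"]])   # suppressor moving up
  expect_false(got[["ONC2"]])   # below fold-change threshold
  expect_true(got[["SUP2"]])
  expect_equal(out$direction[out$gene == "SUP2"], "down")

  # significance is required too
  expr$fdr <- 0.5
  out2 <- suppressMessages(annotate_drivers(expr, catalog))
  expect_false(any(out2$dysregulated))
  expect_error(annotate_drivers(expr, data.frame(gene = "X", role = "tf")),
               "role")
})

test_that("edge consistency encodes the activation/inhibition algebra", {
  expect_true(edge_consistent("activation", "up", "up"))
  expect_true(edge_consistent("activation", "down", "down"))
  expect_false(edge_consistent("activation", "up", "down"))
  expect_false(edge_consistent("inhibition", "up", "up"))
  expect_true(edge_consistent("inhibition", "up", "down"))
  expect_true(edge_consistent("inhibition", "down", "up"))
  expect_error(edge_consistent("binding", "up", "up"), "sign")
})

test_that("the methylation-driven predicate combines all four constraints", {
  meth <- make_meth(c("A", "B", "C", "D"), c(40, 40, 20, 40),
                    fdr = c(0.01, 0.01, 0.01, 0.5))
  expr <- make_expr(c("A", "B", "C", "D"), c(-2, 2, -2, -2))
  expect_true(methylation_driven("A", meth, expr, 32.2)[["A"]])
  expect_false(methylation_driven("B", meth, expr, 32.2)[["B"]])  # not inverse
  expect_false(methylation_driven("C", meth, expr, 32.2)[["C"]])  # small change
  expect_true(methylation_driven("C", meth, expr, 15)[["C"]])
  expect_false(methylation_driven("D", meth, expr, 32.2)[["D"]])  # meth not sig
  expect_false(methylation_driven("Z", meth, expr, 32.2)[["Z"]])  # missing
  # weak expression fails the magnitude rule
  expr2 <- make_expr("A", -0.5)
  expect_false(methylation_driven("A", meth, expr2, 32.2)[["A"]])
})

test_that("search recovers the planted chain and rejects inconsistent routes", {
  # D(up) -act- A(up) -inh- B(down); B has a large positive meth change.
  # Shortcut D-B exists but with the sign that is inconsistent.
  edges <- make_edges(c("D", "A", "D"), c("A", "B", "B"),
                      c("activation", "inhibition", "activation"))
  expr <- make_expr(c("D", "A", "B"), c(2, 1.5, -2))
  meth <- make_meth(c("D", "A", "B"), c(-5, 3, 60))
  g <- build_graph(edges)
  out <- search_from_driver(g, "D", meth, expr, meth_threshold = 32.2)
  expect_equal(nrow(out), 1)
  expect_equal(out$terminal, "B")
  expect_equal(out$distance, 2)
  expect_equal(out$nodes, "D_A_B")
  expect_equal(out$signs, "activation_inhibition")

  # the consistent shortcut would win instead
  edges2 <- make_edges(c("D", "A", "D"), c("A", "B", "B"),
                       c("activation", "inhibition", "inhibition"))
  out2 <- search_from_driver(build_graph(edges2), "D", meth, expr)
  expect_equal(out2$distance, 1)
  expect_equal(out2$nodes, "D_B")

  # a single inconsistent link with no alternative: nothing is found
  edges3 <- make_edges(c("D", "A"), c("A", "B"),
                       c("inhibition", "inhibition"))
  out3 <- search_from_driver(build_graph(edges3), "D", meth, expr)
  expect_equal(nrow(out3), 0)

  # driver that is itself methylation-driven: distance 0
  meth0 <- make_meth("D", -40)
  expr0 <- make_expr("D", 2)
  out0 <- search_from_driver(build_graph(edges), "D", meth0, expr0)
  expect_equal(out0$distance, 0)
  expect_equal(out0$nodes, "D")
})

test_that("equally short parallel paths are all reported", {
  # diamond: D-A-T and D-B-T, both consistent
  edges <- make_edges(c("D", "A", "D", "B"), c("A", "T", "B", "T"),
                      rep("activation", 4))
  expr <- make_expr(c("D", "A", "B", "T"), c(2, 1.5, 1.2, 2))
  meth <- make_meth(c("D", "A", "B", "T"), c(1, 1, 1, -60))
  out <- search_from_driver(build_graph(edges), "D", meth, expr)
  expect_equal(nrow(out), 2)
  expect_setequal(out$nodes, c("D_A_T", "D_B_T"))
  expect_equal(unique(out$distance), 2)
})

test_that("intermediates need significance but not magnitude unless strict", {
  edges <- make_edges(c("D", "A"), c("A", "T"), rep("activation", 2))
  expr <- make_expr(c("D", "A", "T"), c(2, 0.4, 2))  # A weakly up
  meth <- make_meth(c("D", "A", "T"), c(1, 1, -60))
  g <- build_graph(edges)
  out <- search_from_driver(g, "D", meth, expr)
  expect_equal(out$distance, 2)
  strict <- search_from_driver(g, "D", meth, expr, strict = TRUE)
  expect_equal(nrow(strict), 0)
  # a non-significant intermediate blocks the path in either mode
  expr2 <- make_expr(c("D", "A", "T"), c(2, 1.4, 2), fdr = c(0.01, 0.5, 0.01))
  expect_equal(nrow(search_from_driver(g, "D", meth, expr2)), 0)
})

test_that("shortest-distance retention keeps ties and drops longer paths", {
  paths <- data.frame(driver = c("D", "D", "D", "E", "E"),
                      terminal = c("t1", "t2", "t3", "t4", "t5"),
                      distance = c(2, 2, 3, 1, 4),
                      nodes = "x", signs = "y", stringsAsFactors = FALSE)
  out <- shortest_retention(paths)
  expect_setequal(out$terminal[out$driver == "D"], c("t1", "t2"))
  expect_identical(out$terminal[out$driver == "E"], "t4")
  single <- paths[3, ]
  expect_equal(shortest_retention(single), single, ignore_attr = TRUE)
})

test_that("distance summaries count class genes, close genes and averages", {
  paths <- data.frame(driver = "D",
                      terminal = c("a", "a", "b", "c"),
                      distance = c(1, 3, 1, 5),
                      nodes = "x", signs = "y", stringsAsFactors = FALSE)
  s <- summarize_distances(paths, c("a", "b", "c", "d"))
  expect_equal(s$n_class_genes, 4)
  expect_equal(s$n_with_path, 3)
  expect_equal(s$n_close, 2)           # c is at distance 5
  expect_equal(s$close_proportion, 2 / 3)
  expect_equal(s$avg_distance, 1)      # min distances of close genes: 1, 1

  none <- summarize_distances(paths, "zzz")
  expect_equal(none$n_with_path, 0)
  expect_equal(none$close_proportion, 0)
  expect_true(is.na(none$avg_distance))

  all_reached <- summarize_distances(paths, c("a", "b", "c"),
                                     avg_over = "reached")
  expect_equal(all_reached$avg_distance, mean(c(1, 1, 5)))
})

test_that("breadth-first results equal exhaustive simple-path enumeration", {
  skip_if_not_installed("igraph")
  for (seed in 1:60) {
    case <- random_search_case(seed, n_nodes = sample(5:12, 1))
    for (thr in c(15, 32.2)) {
      got <- package_min_distances(case, thr)
      want <- oracle_min_distances(case, thr)
      want <- want[order(names(want))]
      expect_identical(got, want, info = paste("seed", seed, "thr", thr))
    }
  }
})

test_that("terminal sets shrink monotonically as the threshold rises", {
  for (seed in 101:130) {
    case <- random_search_case(seed, n_nodes = 12, n_edges = 24)
    t_low <- names(package_min_distances(case, 15))
    t_high <- names(package_min_distances(case, 32.2))
    expect_true(all(t_high %in% t_low), info = paste("seed", seed))
  }
})

test_that("search output is invariant under gene relabeling", {
  relabel <- function(x, map) unname(map[x])
  case <- random_search_case(7, n_nodes = 10)
  base <- package_min_distances(case, 15)

  set.seed(8)
  map <- setNames(paste0("Z", sample(10)), paste0("N", 1:10))
  case2 <- case
  case2$edges$gene_a <- relabel(case$edges$gene_a, map)
  case2$edges$gene_b <- relabel(case$edges$gene_b, map)
  case2$expr$gene <- relabel(case$expr$gene, map)
  case2$meth$gene <- relabel(case$meth$gene, map)
  case2$driver <- unname(map[case$driver])
  got <- package_min_distances(case2, 15)
  want <- setNames(as.integer(base), unname(map[names(base)]))
  expect_identical(got, want[order(names(want))])
})
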