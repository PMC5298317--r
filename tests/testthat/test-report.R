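# Result tables: class counts, cross-cohort sharing, averages, overlaps.

test_that("class counts split jointly altered genes at the two thresholds", {
  gm <- make_meth(c("a", "b", "c"), c(40, 20, 10))
  expr <- make_expr(c("a", "b", "c"), c(-2, 2, -2))
  expect_equal(class_counts(gm, expr), c(n_large = 1L, n_normal = 1L))

  empty <- gm[0, ]
  expect_equal(class_counts(empty, expr), c(n_large = 0L, n_normal = 0L))

  low <- make_meth(c("a", "b"), c(5, -9))
  expect_equal(class_counts(low, expr[1:2, ]),
               c(n_large = 0L, n_normal = 0L))

  # genes failing the expression screen never count
  weak_expr <- make_expr(c("a", "b", "c"), c(-0.5, 0.2, -0.1))
  expect_equal(class_counts(gm, weak_expr),
               c(n_large = 0L, n_normal = 0L))
  expect_error(class_counts(gm, expr, threshold = 10, baseline = 15),
               "baseline")

  sets <- class_gene_sets(gm, expr)
  expect_identical(sets$large, "a")
  expect_identical(sets$normal, "b")
})

test_that("cross-cohort table reproduces a five-cohort shared-driver row", {
  mkpaths <- function(driver, dist) {
    data.frame(driver = driver, terminal = paste0("t", seq_along(dist)),
               distance = dist, nodes = "x", signs = "y",
               stringsAsFactors = FALSE)
  }
  per <- list(
    THCA = mkpaths("AGTR1", 3),
    CHOL = rbind(mkpaths("AGTR1", c(2, 4)), mkpaths("ONLY1", 1)),
    COAD = mkpaths("AGTR1", 2),
    KIRP = mkpaths("OTHER", 5),      # distance above 3: excluded
    LUSC = mkpaths("AGTR1", 2),
    LIHC = mkpaths("AGTR1", 1))
  out <- cross_cancer_table(per)
  expect_equal(nrow(out), 1)  # ONLY1 and OTHER fail the sharing rule
  row <- out[out$driver == "AGTR1", ]
  expect_equal(unlist(row[c("THCA", "CHOL", "COAD", "LUSC", "LIHC")]),
               c(THCA = 3L, CHOL = 2L, COAD = 2L, LUSC = 2L, LIHC = 1L))
  expect_true(is.na(row$KIRP))
  expect_equal(row$n_datasets, 5L)

  empty <- cross_cancer_table(list(A = mkpaths("X", 2)[0, ],
                                   B = mkpaths("X", 2)[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("published six-cohort summaries reproduce the printed averages", {
  path <- system.file("extdata", "tcga_cohort_path_summary.tsv",
                      package = "methdriver")
  rows <- read.delim(path)
  avg <- averages_summary(rows, exclude_from_distance = "THCA")
  cs <- avg$class_summary
  expect_equal(cs$mean_close_proportion_pct[cs$meth_class == "large"], 7.83)
  expect_equal(cs$mean_close_proportion_pct[cs$meth_class == "normal"], 3.00)
  expect_equal(cs$mean_avg_distance[cs$meth_class == "large"], 1.95)
  expect_equal(cs$mean_avg_distance[cs$meth_class == "normal"], 2.09)

  props <- avg$proportions
  expect_equal(props$proportion[props$dataset == "CHOL" &
                                  props$meth_class == "large"], 0.11)
  dd <- avg$distance_difference
  expect_equal(dd$difference[dd$dataset == "THCA"], 0.37)
  expect_equal(dd$difference[dd$dataset == "LIHC"], -0.24)

  # raw (unrounded) ratios give a visibly different average
  raw <- averages_summary(rows, rounded = FALSE,
                          exclude_from_distance = "THCA")
  rcs <- raw$class_summary
  expect_equal(rcs$mean_close_proportion_pct[rcs$meth_class == "large"],
               7.94)
  expect_equal(rcs$mean_close_proportion_pct[rcs$meth_class == "normal"],
               3.14)
})

test_that("intersection counts partition the union by membership pattern", {
  out <- intersection_counts(list(A = c("g1", "g2"), B = "g2"))
  expect_equal(out$count[out$pattern == "A"], 1)
  expect_equal(out$count[out$pattern == "A&B"], 1)
  expect_equal(attr(out, "set_totals"), c(A = 2, B = 1))

  disjoint <- intersection_counts(list(A = c("x", "y"), B = "z"))
  expect_false(any(grepl("&", disjoint$pattern)))

  identical_sets <- intersection_counts(list(A = c("x", "y"),
                                             B = c("x", "y")))
  expect_equal(nrow(identical_sets), 1)
  expect_equal(identical_sets$pattern, "A&B")
  expect_equal(identical_sets$count, 2)

  # the counts always partition the union
  set.seed(7)
  for (i in 1:10) {
    sets <- lapply(1:4, function(j) {
      sample(paste0("g", 1:15), sample(0:10, 1))
    })
    names(sets) <- LETTERS[1:4]
    out <- intersection_counts(sets)
    expect_equal(sum(out$count), length(unique(unlist(sets))))
  }
  expect_error(intersection_counts(list()), "at least one")
})

test_that("the shipped shared-driver table has the cross-cohort row shape", {
  path <- system.file("extdata", "tcga_shared_driver_steps.tsv",
                      package = "methdriver")
  tab <- read.delim(path, na.strings = "-", check.names = FALSE)
  dist_cols <- setdiff(names(tab), "driver")
  mat <- as.matrix(tab[dist_cols])
  # only close distances appear, and every driver is shared by >= 2 cohorts
  expect_true(all(mat[!is.na(mat)] %in% 0:3))
  n_ds <- rowSums(!is.na(mat))
  expect_true(all(n_ds >= 2))
  # the two most widely shared drivers span five cohorts
  expect_setequal(tab$driver[n_ds == 5], c("AGTR1", "IGF1"))
  # feeding the per-cohort minima back through the table builder
  # reconstructs the same rows
  per <- lapply(dist_cols, function(d) {
    keep <- !is.na(tab[[d]])
    data.frame(driver = tab$driver[keep], terminal = "t",
               distance = tab[[d]][keep], nodes = "x", signs = "y",
               stringsAsFactors = FALSE)
  })
  names(per) <- dist_cols
  rebuilt <- cross_cancer_table(per)
  expect_setequal(rebuilt$driver, tab$driver)
  idx <- match(tab$driver, rebuilt$driver)
  expect_equal(unname(as.matrix(rebuilt[idx, dist_cols])),
               unname(mat))
})
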