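# Single-gene marker statistics: negations, binarization, TP/TN, ranking.

cells6 <- paste0("c", 1:6)
cl6 <- setNames(c("K", "K", "K", "C", "C", "C"), cells6)

test_that("add_negations appends -1x tracks as free-standing genes", {
  m <- fixture_matrix(c(2, 0, 1), "g1", paste0("c", 1:3))
  out <- add_negations(m)
  expect_identical(dim(out), c(2L, 3L))
  expect_equal(unname(out["g1_negation", ]), c(-2, 0, -1))
  m5 <- fixture_matrix(rnorm(15), paste0("g", 1:5), paste0("c", 1:3))
  expect_identical(nrow(add_negations(m5)), 10L)
  clash <- fixture_matrix(c(1, 2, 1, 2), c("a", "a_negation"), c("c1", "c2"))
  expect_error(add_negations(clash), "collision")
})

test_that("clean marker: threshold, cutoff, binarization and rates", {
  mat <- fixture_matrix(c(5, 4, 3, 0, 0, 0), "gA", cells6)
  gs <- gene_stats(mat, cl6, "K", X = 1, L = 6)
  s <- gs$stats
  expect_identical(s$threshold_index, 3L)
  expect_equal(s$cutoff, 0)
  expect_equal(s$tp_rate, 1)
  expect_equal(s$tn_rate, 1)
  expect_equal(s$stat, 1 / 20)            # 1 / C(6, 3)
  expect_identical(unname(gs$binary["gA", ]),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("slide-up excludes all cells tied at the cutoff value", {
  # K = {5, 4, 3}; two background cells tie the boundary value 3. The
  # minimum lands at t* = 2 (tail 0.2 vs 0.5 elsewhere), the cutoff is the
  # tied value 3, and strict comparison drops the in-cluster 3 as well.
  mat <- fixture_matrix(c(5, 4, 3, 3, 3, 0), "gB", cells6)
  gs <- gene_stats(mat, cl6, "K", X = 1, L = 6)
  expect_identical(gs$stats$threshold_index, 2L)
  expect_equal(gs$stats$cutoff, 3)
  expect_equal(gs$stats$tp_rate, 2 / 3)
  expect_identical(unname(gs$binary["gB", ]),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("boundary tie inside a run follows the conservative ordering", {
  # counterpart fixture: with non-K-first ties the minimum is at t* = 4 and
  # the cutoff 0, so every value-3 cell is positive (see decisions ledger)
  mat <- fixture_matrix(c(5, 3, 3, 3, 0, 0), "gC", cells6)
  gs <- gene_stats(mat, cl6, "K", X = 1, L = 6)
  expect_identical(gs$stats$threshold_index, 4L)
  expect_equal(gs$stats$cutoff, 0)
  expect_equal(gs$stats$tp_rate, 1)
})

test_that("constant gene is degenerate and later filtered", {
  mat <- rbind(fixture_matrix(c(5, 4, 3, 0, 0, 0), "gA", cells6),
               gD = rep(2, 6))
  gs <- gene_stats(mat, cl6, "K", X = 1, L = 6)
  gd <- gs$stats[gs$stats$gene == "gD", ]
  expect_equal(gd$xlmhg_pvalue, 1)
  expect_equal(gd$tp_rate, 0)
  tabs <- rank_single_genes(gs)
  expect_false("gD" %in% tabs$ranked$gene)
  expect_true("gD" %in% tabs$full$gene)
})

test_that("negation of an absence marker scores perfect TP in the cluster", {
  mat <- add_negations(fixture_matrix(c(0, 0, 2, 3, 4, 5), "g", cells6))
  gs <- gene_stats(mat, cl6, "K", X = 1, L = 6)
  neg <- gs$stats[gs$stats$gene == "g_negation", ]
  expect_equal(neg$tp_rate, 1)
  expect_equal(neg$tn_rate, 1)
  expect_equal(neg$log2_fc, -gs$stats$log2_fc[gs$stats$gene == "g"])
  # the negation, not the parent, tops the ranking on this absence fixture
  tabs <- rank_single_genes(gs)
  expect_identical(tabs$ranked$gene[1], "g_negation")
  expect_gt(match("g", c(tabs$ranked$gene, "g")), 1)
})

test_that("TP below 15 percent or negation TN below 50 percent is filtered", {
  stats <- data.frame(
    gene = c("a", "b", "c_negation", "d"),
    xlmhg_pvalue = c(0.01, 0.02, 0.03, 0.04),
    stat = 0.01, threshold_index = 2L, cutoff = 0,
    tp_rate = c(0.50, 0.10, 0.40, 0.20),
    tn_rate = c(0.9, 0.9, 0.40, 0.9),
    log2_fc = c(2, 1, -3, 0.5),
    is_negation = c(FALSE, FALSE, TRUE, FALSE))
  tabs <- rank_single_genes(stats)
  expect_false("b" %in% tabs$ranked$gene)            # TP 0.10 < 0.15
  expect_false("c_negation" %in% tabs$ranked$gene)   # TN 0.40 < 0.50
  expect_setequal(tabs$full$gene, stats$gene)
  expect_identical(tabs$ranked_positive$gene, tabs$ranked$gene)
})

test_that("aggregated rank averages competition ranks and sorts deterministically", {
  stats <- data.frame(
    gene = c("a", "b", "c"),
    xlmhg_pvalue = c(1e-5, 1e-3, 1e-4),
    stat = 1e-5, threshold_index = 2L, cutoff = 0,
    tp_rate = 0.9, tn_rate = 0.9,
    log2_fc = c(1.0, 3.0, 2.0),
    is_negation = FALSE)
  tabs <- rank_single_genes(stats)
  a <- tabs$ranked[tabs$ranked$gene == "a", ]
  expect_equal(a$pvalue_rank, 1)
  expect_equal(a$fc_rank, 3)
  expect_equal(a$aggregated_rank, 2.0)
  # all aggregated ranks tie at 2.0 here; order falls back to p-value
  expect_identical(tabs$ranked$gene, c("a", "c", "b"))
})

test_that("TP count reaches X unless slide-up excluded tied cells", {
  set.seed(21)
  for (i in 1:15) {
    n <- 40
    m <- 10
    cl <- setNames(rep(c("K", "C"), c(m, n - m)), paste0("c", 1:n))
    mat <- fixture_matrix(round(c(rnorm(m, 2), rnorm(n - m, 0)), 1),
                          "g", paste0("c", 1:n))
    gs <- gene_stats(mat, cl, "K")
    tp_count <- gs$stats$tp_rate * m
    slid <- gs$stats$threshold_index > 0 &&
      sum(mat > gs$stats$cutoff) < gs$stats$threshold_index
    expect_true(tp_count >= gs$X || slid)
  }
})

test_that("binarization is cluster-specific", {
  set.seed(31)
  n <- 30
  cl <- setNames(rep(c("A", "B", "C"), each = 10), paste0("c", 1:n))
  mat <- fixture_matrix(c(rnorm(10, 5), rnorm(10, 2), rnorm(10, 0)),
                        "g", paste0("c", 1:n))
  gsA <- gene_stats(mat, cl, "A")
  gsB <- gene_stats(mat, cl, "B")
  expect_false(isTRUE(all.equal(gsA$stats$cutoff, gsB$stats$cutoff)))
})
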