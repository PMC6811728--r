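# Panel combinatorics: count matrices, hypergeometric ranking, CCS,
# heuristic candidates, output caps.

test_that("positives_matrices matches hand multiplication and structure", {
  A <- matrix(c(1, 1, 0, 1, 0, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  pm <- positives_matrices(A, c(TRUE, TRUE, FALSE))
  expect_equal(unname(pm$R), matrix(c(2, 1, 1, 2), 2))
  expect_true(all(pm$R_K <= pm$R))
  A0 <- rbind(A, z = c(0, 0, 0))
  pm0 <- positives_matrices(A0, c(TRUE, TRUE, FALSE))
  expect_true(all(pm0$R["z", ] == 0) && all(pm0$R[, "z"] == 0))
  expect_equal(pm0$R, t(pm0$R))
})

test_that("panel_hypergeom matches closed forms and the enumeration oracle", {
  expect_equal(panel_hypergeom(4, 5, 4, 10), 6 / 252)
  expect_equal(panel_hypergeom(0, 0, 3, 10), 1)
  expect_error(panel_hypergeom(5, 4, 6, 10), "inconsistent")
  # enumeration oracle: P(X >= k) by counting column subsets
  for (n in c(8, 10)) for (m in 2:4) for (draw in c(3, 5)) {
    k_obs <- min(m, draw)
    cnt <- sum(vapply(utils::combn(n, draw, simplify = FALSE),
                      function(s) sum(s <= m) >= k_obs, logical(1)))
    expect_equal(panel_hypergeom(k_obs, draw, m, n), cnt / choose(n, draw))
  }
})

test_that("cluster_clear_score sums per-cluster true-negative gains", {
  expect_equal(cluster_clear_score(c(C1 = 40, C2 = 60), c(C1 = 90, C2 = 60)),
               50)
  expect_equal(cluster_clear_score(c(C1 = 40), c(C1 = 40)), 0)
})

test_that("pair/triple/quad counts equal the brute-force AND oracle", {
  fx <- random_binary_fixture(p = 15, n = 50, m = 10, seed = 101)
  for (size in 2:4) {
    tab <- switch(as.character(size),
                  "2" = rank_pairs(fx$fb, fx$clusters, "K"),
                  "3" = rank_triples(fx$fb),
                  "4" = rank_quads(fx$fb))
    expect_equal(nrow(tab), choose(15, size))
    expect_identical(anyDuplicated(panel_keys(tab)), 0L)
    oracle <- panel_count_oracle(fx$fb$A, fx$fb$inK, size)
    mt <- match(oracle$key, panel_keys(tab))
    expect_false(anyNA(mt))
    expect_equal(tab$positives_total[mt], oracle$total)
    expect_equal(tab$positives_in_K[mt], oracle$in_K)
  }
})

test_that("panel records are internally consistent and CCS nonnegative", {
  fx <- random_binary_fixture(p = 10, n = 40, m = 8, seed = 7)
  pairs <- rank_pairs(fx$fb, fx$clusters, "K")
  expect_true(all(pairs$positives_in_K <= pairs$positives_total))
  singles <- diag(fx$fb$A %*% t(fx$fb$A))
  lim <- pmin(singles[pairs$gene_1], singles[pairs$gene_2])
  expect_true(all(pairs$positives_total <= lim))
  expect_true(all(pairs$ccs >= -1e-9, na.rm = TRUE))
})

test_that("TP is non-increasing and TN non-decreasing along nested panels", {
  fx <- random_binary_fixture(p = 8, n = 40, m = 8, seed = 55)
  pairs <- rank_pairs(fx$fb, fx$clusters, "K")
  triples <- rank_triples(fx$fb)
  quads <- rank_quads(fx$fb)
  kp <- panel_keys(pairs)
  kt <- panel_keys(triples)
  kq <- panel_keys(quads)
  for (qi in seq_len(nrow(quads))) {
    qg <- sort(unlist(quads[qi, paste0("gene_", 1:4)], use.names = FALSE))
    for (drop in 1:4) {
      tkey <- paste(qg[-drop], collapse = "|")
      ti <- match(tkey, kt)
      expect_lte(quads$tp_rate[qi], triples$tp_rate[ti] + 1e-12)
      expect_gte(quads$tn_rate[qi], triples$tn_rate[ti] - 1e-12)
    }
  }
  for (ti in seq_len(nrow(triples))) {
    tg <- sort(unlist(triples[ti, paste0("gene_", 1:3)], use.names = FALSE))
    for (drop in 1:3) {
      pkey <- paste(tg[-drop], collapse = "|")
      pi <- match(pkey, kp)
      expect_lte(triples$tp_rate[ti], pairs$tp_rate[pi] + 1e-12)
      expect_gte(triples$tn_rate[ti], pairs$tn_rate[pi] - 1e-12)
    }
  }
})

test_that("a clearing partner outranks redundant pairs through the CCS", {
  # gene A marks K plus contaminating cluster C1; gene B is negative on C1.
  # The pair (A, B) clears C1, so its CCS must exceed that of (A, D) where D
  # duplicates A; with equal hypergeometric p-values the CCS decides.
  cells <- sprintf("c%02d", 1:30)
  clusters <- setNames(rep(c("K", "C1", "C2"), each = 10), cells)
  A <- rbind(
    gA = c(rep(1, 10), rep(1, 10), rep(0, 10)),
    gB = c(rep(1, 10), rep(0, 10), rep(1, 10)),
    gD = c(rep(1, 10), rep(1, 10), rep(0, 10)))
  colnames(A) <- cells
  fb <- list(A = A, inK = clusters == "K",
             single_pvalue = c(gA = 1e-6, gB = 1e-4, gD = 1e-3),
             m = 10, n = 30)
  pairs <- rank_pairs(fb, clusters, "K")
  ab <- pairs[pairs$gene_1 == "gA" & pairs$gene_2 == "gB", ]
  ad <- pairs[pairs$gene_1 == "gA" & pairs$gene_2 == "gD", ]
  expect_gt(ab$ccs, ad$ccs)
  expect_equal(ad$ccs, 0)     # adding a duplicate clears nothing
  expect_lt(ab$final_rank, ad$final_rank)
})

test_that("heuristic candidate spaces have the stated cardinalities", {
  expect_identical(nrow(heuristic_candidates(1:3, 10, 2)), 24L)
  expect_identical(nrow(heuristic_candidates(1:3, 10, 3)), 22L)
  expect_identical(nrow(heuristic_candidates(1:3, 10, 4)), 0L)
  expect_equal(nrow(heuristic_candidates(1:10, 10, 2)), choose(10, 2))
  expect_equal(nrow(heuristic_candidates(1:10, 10, 3)), choose(10, 3))
})

test_that("candidate spaces are nested in the core size", {
  p <- 9
  keys <- function(cand) apply(cand, 1, paste, collapse = "|")
  for (size in 2:3) {
    prev <- character(0)
    for (N in 2:p) {
      cur <- keys(heuristic_candidates(seq_len(N), p, size))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("results are independent of the evaluation block size", {
  fx <- random_binary_fixture(p = 10, n = 30, m = 6, seed = 77)
  t_big <- rank_triples(fx$fb, block_size = 100000L)
  t_small <- rank_triples(fx$fb, block_size = 7L)
  expect_equal(t_big, t_small)
  q_big <- rank_quads(fx$fb, block_size = 100000L)
  q_small <- rank_quads(fx$fb, block_size = 5L)
  expect_equal(q_big, q_small)
})

test_that("output caps bound lead-gene plots and per-gene emissions", {
  df <- data.frame(gene_1 = "lead", gene_2 = sprintf("p%03d", 1:30),
                   lead = "lead", stringsAsFactors = FALSE)
  lim <- limit_panels(df, plot_cap = 10, gene_cap = 200)
  expect_identical(sum(lim$plot), 10L)
  expect_identical(sum(lim$emit), 30L)
  df2 <- data.frame(gene_1 = "g", gene_2 = sprintf("q%03d", 1:500),
                    lead = sprintf("q%03d", 1:500), stringsAsFactors = FALSE)
  lim2 <- limit_panels(df2)
  expect_identical(sum(lim2$emit), 200L)
  empty <- limit_panels(df2[0, ])
  expect_identical(nrow(empty), 0L)
})
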