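# Independent oracles and fixture builders shared across the suite.
# The oracles deliberately avoid the code paths they check: the XL-mHG
# p-value oracle enumerates arrangements, the panel oracle ANDs matrix
# columns directly.

# All C(n, m) arrangements of m ones among n positions, as an n x C(n, m)
# 0/1 matrix (one arrangement per column).
all_arrangements <- function(n, m) {
  pos <- utils::combn(n, m)
  apply(pos, 2L, function(idx) {
    lab <- integer(n)
    lab[idx] <- 1L
    lab
  })
}

# XL-mHG statistic of a fixed 0/1 label vector (values are implied ranks).
stat_of_labels <- function(labels, X, L) {
  n <- length(labels)
  ranked <- structure(list(labels = labels, values = seq(n, 1),
                           n = n, m = sum(labels)),
                      class = "ranked_membership")
  mhg_statistic(ranked, X, L)$stat
}

# Exhaustive-permutation p-value oracle: fraction of arrangements whose
# XL-mHG statistic is at most s (same comparison slack as the DP).
pvalue_oracle <- function(s, n, m, X, L) {
  stats <- arrangement_stats(all_arrangements(n, m), X, L)
  mean(stats <= s * (1 + 1e-12))
}

arrangement_stats <- function(arr, X, L) {
  apply(arr, 2L, function(lab) stat_of_labels(lab, X, L))
}

# Brute-force AND counts over matrix columns for every size-k combination.
panel_count_oracle <- function(A, inK, size) {
  cmb <- t(utils::combn(rownames(A), size))
  counts <- t(apply(cmb, 1L, function(g) {
    v <- apply(A[g, , drop = FALSE], 2L, prod)
    c(total = sum(v), in_K = sum(v[inK]))
  }))
  data.frame(key = apply(cmb, 1L, function(g) paste(sort(g), collapse = "|")),
             total = counts[, "total"], in_K = counts[, "in_K"],
             stringsAsFactors = FALSE)
}

panel_keys <- function(df) {
  gm <- as.matrix(df[, grep("^gene_", names(df)), drop = FALSE])
  apply(gm, 1L, function(g) paste(sort(g), collapse = "|"))
}

# Small named genes-by-cells matrix from row-major values.
fixture_matrix <- function(vals, genes, cells) {
  matrix(vals, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, cells))
}

# Random binary fixture with gene/cell names and a cluster assignment over
# one target and two background clusters.
random_binary_fixture <- function(p, n, m, seed, density = 0.4) {
  set.seed(seed)
  A <- matrix(rbinom(p * n, 1L, density), p, n,
              dimnames = list(sprintf("g%02d", seq_len(p)),
                              sprintf("c%02d", seq_len(n))))
  storage.mode(A) <- "double"
  inK <- c(rep(TRUE, m), rep(FALSE, n - m))
  nbg <- n - m
  clusters <- setNames(c(rep("K", m),
                         rep(c("C1", "C2"), c(ceiling(nbg / 2),
                                              floor(nbg / 2)))),
                       colnames(A))
  fb <- list(A = A, inK = inK,
             single_pvalue = setNames(runif(p), rownames(A)),
             m = m, n = n)
  list(fb = fb, clusters = clusters)
}
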