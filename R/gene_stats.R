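# Per-cluster single-gene marker statistics: negation tracks, XL-mHG
# thresholds, slide-up binarization, TP/TN rates, log2 fold change and
# rank aggregation.

.negation_suffix <- "_negation"

.is_negation <- function(ids) endsWith(ids, .negation_suffix)

#' Append negation tracks to an expression matrix
#'
#' For every gene `g` a free-standing track `g_negation` with expression
#' `-1 * g` is added, so that *absence* of expression can act as a marker.
#' Negation tracks are treated as ordinary genes by all downstream analysis.
#'
#' @param mat Genes-by-cells numeric matrix with unique rownames (gene ids)
#'   and colnames (cell ids).
#' @return A matrix with `2p` rows; the new rows carry the `_negation` suffix.
#' @export
add_negations <- function(mat) {
  .check_expression_matrix(mat)
  neg <- -mat
  rownames(neg) <- paste0(rownames(mat), .negation_suffix)
  if (any(rownames(neg) %in% rownames(mat)))
    stop("gene id collision: input already contains '", .negation_suffix,
         "' ids that clash with generated negation tracks")
  rbind(mat, neg)
}

.check_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("expression matrix needs unique gene ids as rownames")
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)))
    stop("expression matrix needs unique cell ids as colnames")
  if (anyNA(mat)) stop("expression matrix contains NA/NaN")
  invisible(TRUE)
}

.check_clusters <- function(clusters, mat) {
  if (is.null(names(clusters)))
    stop("'clusters' must be a named vector (cell id -> cluster label)")
  missing <- setdiff(colnames(mat), names(clusters))
  if (length(missing) > 0L)
    stop("cells without cluster assignment: ", paste(utils::head(missing, 5),
         collapse = ", "))
  invisible(TRUE)
}

#' Single-gene XL-mHG statistics and binarization for one cluster
#'
#' Runs the XL-mHG test for every gene (including any negation tracks already
#' present) against cluster `K` versus all remaining cells merged, derives the
#' cluster-specific expression cutoff (slide-up policy: a cell is positive iff
#' its expression strictly exceeds the value at rank `threshold_index + 1`),
#' and computes true-positive/true-negative rates and log2 fold change of
#' means with pseudocount `delta`. For a negation track whose parent gene is
#' present, the log2 fold change is the parent's with the sign flipped.
#'
#' @param mat Genes-by-cells numeric matrix (see [add_negations()]).
#' @param clusters Named vector mapping cell id to cluster label.
#' @param K Cluster label of interest.
#' @param X,L XL-mHG parameters; defaults from [default_xl()] for `|K|`.
#' @param delta Pseudocount for the fold change (input scale).
#' @param tie_policy Passed to [rank_membership()].
#' @return A list of class `gene_stats` with elements `stats` (a data.frame
#'   with one row per gene: `gene`, `xlmhg_pvalue`, `stat`, `threshold_index`,
#'   `cutoff`, `tp_rate`, `tn_rate`, `log2_fc`, `is_negation`), `binary`
#'   (genes-by-cells logical matrix of positive calls), and run metadata
#'   (`K`, `m`, `n`, `X`, `L`).
#' @export
gene_stats <- function(mat, clusters, K, X = NULL, L = NULL, delta = 1e-6,
                       tie_policy = "conservative") {
  .check_expression_matrix(mat)
  .check_clusters(clusters, mat)
  inK <- clusters[colnames(mat)] == K
  m <- sum(inK)
  n <- ncol(mat)
  if (m == 0L) stop("cluster '", K, "' is empty")
  if (m == n) stop("cluster '", K, "' contains every cell; no background")
  if (is.null(X) || is.null(L)) {
    d <- default_xl(m, n)
    if (is.null(X)) X <- d$X
    if (is.null(L)) L <- d$L
  }
  genes <- rownames(mat)
  p <- length(genes)
  pvalue <- stat <- cutoff <- tp <- tn <- numeric(p)
  tindex <- integer(p)
  binary <- matrix(FALSE, p, n, dimnames = dimnames(mat))
  for (i in seq_len(p)) {
    res <- xlmhg_test(mat[i, ], inK, X = X, L = L, tie_policy = tie_policy)
    pos <- mat[i, ] > res$cutoff
    pvalue[i] <- res$pvalue
    stat[i] <- res$stat
    tindex[i] <- res$threshold_index
    cutoff[i] <- res$cutoff
    tp[i] <- sum(pos & inK) / m
    tn[i] <- sum(!pos & !inK) / (n - m)
    binary[i, ] <- pos
  }
  is_neg <- .is_negation(genes)
  mean_K <- rowMeans(mat[, inK, drop = FALSE])
  mean_bg <- rowMeans(mat[, !inK, drop = FALSE])
  lfc <- rep(NA_real_, p)
  ok <- mean_K + delta > 0 & mean_bg + delta > 0
  lfc[ok] <- log2((mean_K[ok] + delta) / (mean_bg[ok] + delta))
  parent <- sub(paste0(.negation_suffix, "$"), "", genes)
  has_parent <- is_neg & parent %in% genes
  lfc[has_parent] <- -lfc[match(parent[has_parent], genes)]
  stats <- data.frame(gene = genes, xlmhg_pvalue = pvalue, stat = stat,
                      threshold_index = tindex, cutoff = cutoff,
                      tp_rate = tp, tn_rate = tn, log2_fc = lfc,
                      is_negation = is_neg, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(stats = stats, binary = binary, K = K, m = m, n = n,
                 X = X, L = L, inK = inK),
            class = "gene_stats")
}

.competition_rank <- function(x) rank(x, ties.method = "min")

#' Rank and filter single-gene markers
#'
#' Filters out genes with a true-positive rate below `tp_min` (default 15%)
#' and negation tracks with a true-negative rate below `neg_tn_min` (default
#' 50%), then ranks the survivors by the arithmetic average of the XL-mHG
#' p-value rank and the absolute log2 fold change rank (competition ranking,
#' ties "1,2,2,4"). The final ordering breaks aggregated-rank ties by p-value
#' and then gene id.
#'
#' @param gs A [gene_stats()] object (or its `stats` data.frame).
#' @param tp_min Minimum true-positive rate to keep a gene.
#' @param neg_tn_min Minimum true-negative rate to keep a negation track.
#' @return A list with `ranked` (all genes passing the filters, sorted),
#'   `ranked_positive` (the same restricted to non-negation genes) and
#'   `full` (every gene, unranked and unfiltered).
#' @export
rank_single_genes <- function(gs, tp_min = 0.15, neg_tn_min = 0.5) {
  stats <- if (inherits(gs, "gene_stats")) gs$stats else gs
  keep <- stats$tp_rate >= tp_min &
    !(stats$is_negation & stats$tn_rate < neg_tn_min)
  flt <- stats[keep, , drop = FALSE]
  if (nrow(flt) > 0L) {
    flt$pvalue_rank <- .competition_rank(flt$xlmhg_pvalue)
    abs_fc <- abs(flt$log2_fc)
    abs_fc[is.na(abs_fc)] <- -Inf  # unranked fold changes go last
    flt$fc_rank <- .competition_rank(-abs_fc)
    flt$aggregated_rank <- (flt$pvalue_rank + flt$fc_rank) / 2
    ord <- order(flt$aggregated_rank, flt$xlmhg_pvalue, flt$gene,
                 method = "radix")
    flt <- flt[ord, , drop = FALSE]
    flt$rank <- seq_len(nrow(flt))
  } else {
    flt$pvalue_rank <- flt$fc_rank <- flt$aggregated_rank <- numeric(0)
    flt$rank <- integer(0)
  }
  rownames(flt) <- NULL
  pos <- flt[!flt$is_negation, , drop = FALSE]
  rownames(pos) <- NULL
  list(ranked = flt, ranked_positive = pos, full = stats)
}
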