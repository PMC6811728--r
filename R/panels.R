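# Exact and heuristic enumeration and ranking of 2-, 3- and 4-gene AND-panels
# from the cluster-specific binarized expression matrix.

#' Restrict a binarized matrix to genes usable in panels
#'
#' Keeps genes whose true-positive rate for the cluster is at least `tp_min`
#' (default 15%), the precondition for panel enumeration.
#'
#' @param gs A [gene_stats()] object.
#' @param tp_min Minimum true-positive rate.
#' @return A list with `A` (filtered genes-by-cells 0/1 matrix), `inK`
#'   (logical cell mask for the cluster), `single_pvalue` (named XL-mHG
#'   p-values of the retained genes), `m`, `n`.
#' @export
filter_binary <- function(gs, tp_min = 0.15) {
  stopifnot(inherits(gs, "gene_stats"))
  keep <- gs$stats$tp_rate >= tp_min
  A <- gs$binary[keep, , drop = FALSE]
  storage.mode(A) <- "double"
  pv <- gs$stats$xlmhg_pvalue[keep]
  names(pv) <- gs$stats$gene[keep]
  list(A = A, inK = gs$inK, single_pvalue = pv, m = gs$m, n = gs$n)
}

#' Pairwise co-positivity count matrices
#'
#' `R = A %*% t(A)`: entry (i, j) counts the cells positive for both gene i
#' and gene j; `R_K` is the same restricted to cells in the cluster.
#'
#' @param A Genes-by-cells 0/1 matrix.
#' @param inK Logical vector marking cluster cells.
#' @return A list with integer matrices `R` and `R_K`.
#' @export
positives_matrices <- function(A, inK) {
  storage.mode(A) <- "double"
  R <- A %*% t(A)
  R_K <- A[, inK, drop = FALSE] %*% t(A[, inK, drop = FALSE])
  list(R = R, R_K = R_K)
}

#' Hypergeometric enrichment p-value for a panel
#'
#' Upper-tail probability `P(X >= positives_in_K)` for
#' `X ~ Hypergeometric(n, m, positives_total)`.
#'
#' @param positives_in_K Cells of the cluster positive for the whole panel.
#' @param positives_total Cells positive for the whole panel.
#' @param m Cluster size.
#' @param n Total number of cells.
#' @export
panel_hypergeom <- function(positives_in_K, positives_total, m, n) {
  if (any(positives_in_K > pmin(positives_total, m)))
    stop("inconsistent counts: positives_in_K exceeds positives_total or m")
  if (any(positives_total > n)) stop("positives_total exceeds n")
  stats::phyper(positives_in_K - 1, m, n - m, positives_total,
                lower.tail = FALSE)
}

#' Cluster Clear Score for a gene pair
#'
#' Sum over non-target clusters of the gain in true-negative percent achieved
#' by the panel relative to its lead gene (the member with the smallest
#' single-gene XL-mHG p-value): `sum_C (TN_C_after - TN_C_before)`, in
#' percentage points. AND-logic can only shrink the positive set, so the
#' score is always nonnegative.
#'
#' @param tn_before Named numeric vector: per-cluster true-negative percent of
#'   the lead gene (clusters other than the target).
#' @param tn_after Same for the full panel.
#' @return The score (percent points).
#' @export
cluster_clear_score <- function(tn_before, tn_after) {
  stopifnot(length(tn_before) == length(tn_after))
  sum(tn_after - tn_before)
}

# Canonical key for a set of gene ids (sorted, pipe-joined).
.panel_key <- function(gene_mat) {
  apply(gene_mat, 1L, function(g) paste(sort(g), collapse = "|"))
}

# Counts of cells (all, in-K) positive for every row of a candidate index
# matrix (one panel per row, columns = gene row-indices into A). Blocked to
# bound memory; results are independent of block size.
.panel_counts <- function(A, inK, cand, block_size = 50000L) {
  M <- nrow(cand)
  total <- inKc <- integer(M)
  if (M == 0L) return(list(total = total, in_K = inKc))
  for (start in seq(1L, M, by = block_size)) {
    idx <- start:min(start + block_size - 1L, M)
    P <- A[cand[idx, 1L], , drop = FALSE]
    for (col in 2L:ncol(cand))
      P <- P * A[cand[idx, col], , drop = FALSE]
    total[idx] <- as.integer(round(rowSums(P)))
    inKc[idx] <- as.integer(round(rowSums(P[, inK, drop = FALSE])))
  }
  list(total = total, in_K = inKc)
}

# All index combinations of the given size, optionally restricted to the
# heuristic candidate set; rows sorted ascending, unique.
.all_combos <- function(p, size) {
  if (p < size) return(matrix(integer(0), 0L, size))
  t(utils::combn(p, size))
}

#' Heuristic candidate panels from a single-gene core set
#'
#' For a panel of size `m`, considers only combinations in which at least
#' `m - 1` genes come from the core set of the top `N` single genes (by
#' XL-mHG p-value performance); for 4-gene panels all four genes must come
#' from the core. With `N >= p` the candidate set equals the exhaustive one.
#'
#' @param core Integer indices (into the gene set) of the top-`N` core genes.
#' @param p Total number of retained genes.
#' @param size Panel size (2, 3 or 4).
#' @return Integer matrix, one candidate per row, columns sorted ascending.
#' @export
heuristic_candidates <- function(core, p, size) {
  core <- sort(unique(as.integer(core)))
  if (length(core) < 1L) stop("core must contain at least one gene")
  stopifnot(size %in% 2:4)
  others <- setdiff(seq_len(p), core)
  if (size == 2L) {
    core_core <- if (length(core) >= 2L) t(utils::combn(core, 2L)) else
      matrix(integer(0), 0L, 2L)
    core_other <- if (length(others)) cbind(
      rep(core, each = length(others)),
      rep(others, times = length(core))) else matrix(integer(0), 0L, 2L)
    cand <- rbind(core_core, core_other)
  } else if (size == 3L) {
    core_pairs <- if (length(core) >= 2L) t(utils::combn(core, 2L)) else
      matrix(integer(0), 0L, 2L)
    with_other <- if (nrow(core_pairs) && length(others))
      cbind(core_pairs[rep(seq_len(nrow(core_pairs)), each = length(others)), ,
                       drop = FALSE],
            rep(others, times = nrow(core_pairs))) else
      matrix(integer(0), 0L, 3L)
    all_core <- if (length(core) >= 3L) t(utils::combn(core, 3L)) else
      matrix(integer(0), 0L, 3L)
    cand <- rbind(with_other, all_core)
  } else {
    if (length(core) < 4L) return(matrix(integer(0), 0L, 4L))
    cand <- t(utils::combn(core, 4L))
  }
  cand <- t(apply(cand, 1L, sort))
  cand <- cand[!duplicated(cand), , drop = FALSE]
  # drop any combination with repeated genes (adjacent equal after sorting)
  if (ncol(cand) > 1L && nrow(cand) > 0L) {
    ok <- rowSums(cand[, -1L, drop = FALSE] ==
                    cand[, -ncol(cand), drop = FALSE]) == 0L
    cand <- cand[ok, , drop = FALSE]
  }
  cand
}

# Shared scoring/assembly for panels of any size given candidate indices.
.score_panels <- function(fb, cand, counts) {
  genes <- rownames(fb$A)
  m <- fb$m; n <- fb$n
  pv <- panel_hypergeom(counts$in_K, counts$total, m, n)
  gm <- matrix(genes[cand], nrow(cand), ncol(cand))
  key <- .panel_key(gm)
  df <- data.frame(gm, stringsAsFactors = FALSE)
  names(df) <- paste0("gene_", seq_len(ncol(cand)))
  df$positives_total <- counts$total
  df$positives_in_K <- counts$in_K
  df$hypergeom_pvalue <- pv
  df$tp_rate <- counts$in_K / m
  df$tn_rate <- 1 - (counts$total - counts$in_K) / (n - m)
  df$key <- key
  df
}

#' Rank 2-gene panels
#'
#' Scores every unordered pair of retained genes (or a heuristic candidate
#' subset) by the hypergeometric enrichment p-value of its AND-positive set,
#' computes the Cluster Clear Score for the top `ccs_top` hypergeometric-ranked
#' pairs, and assigns the final rank as the average of the hypergeometric rank
#' and the CCS rank within that subset (hypergeometric rank alone beyond it).
#'
#' @param fb A [filter_binary()] object.
#' @param clusters Named vector of cluster labels for all cells (used for the
#'   per-cluster true-negative percentages entering the CCS).
#' @param K Target cluster label.
#' @param ccs_top Number of top hypergeometric-ranked pairs receiving a CCS.
#' @param candidates Optional integer matrix of candidate pairs (rows of gene
#'   indices into `fb$A`), e.g. from [heuristic_candidates()]; `NULL` means
#'   exhaustive enumeration via the co-positivity matrices.
#' @param block_size Candidate block size for memory-bounded counting.
#' @return A data.frame of panel records sorted by `final_rank` (ties broken
#'   by p-value, then canonical gene key), with columns `gene_1`, `gene_2`,
#'   counts, `hypergeom_pvalue`, `tp_rate`, `tn_rate`, `lead`, `ccs`,
#'   `hg_rank`, `ccs_rank`, `final_rank`.
#' @export
rank_pairs <- function(fb, clusters, K, ccs_top = 1000L, candidates = NULL,
                       block_size = 50000L) {
  genes <- rownames(fb$A)
  p <- length(genes)
  if (p < 2L) return(.empty_panel_df(2L))
  if (is.null(candidates)) {
    pm <- positives_matrices(fb$A, fb$inK)
    ut <- upper.tri(pm$R)
    ij <- which(ut, arr.ind = TRUE)
    cand <- cbind(ij[, "row"], ij[, "col"])
    counts <- list(total = as.integer(pm$R[ut]), in_K = as.integer(pm$R_K[ut]))
  } else {
    cand <- candidates
    counts <- .panel_counts(fb$A, fb$inK, cand, block_size)
  }
  df <- .score_panels(fb, cand, counts)
  # hypergeometric ranking with deterministic tie-break on the canonical key
  ord <- order(df$hypergeom_pvalue, df$key, method = "radix")
  df <- df[ord, , drop = FALSE]
  cand <- cand[ord, , drop = FALSE]
  df$hg_rank <- .competition_rank(df$hypergeom_pvalue)
  # lead gene: member with the smaller single-gene p-value (lexicographic on id
  # for ties)
  p1 <- fb$single_pvalue[df$gene_1]
  p2 <- fb$single_pvalue[df$gene_2]
  lead_is_1 <- p1 < p2 | (p1 == p2 & df$gene_1 < df$gene_2)
  df$lead <- ifelse(lead_is_1, df$gene_1, df$gene_2)
  df$ccs <- NA_real_
  top <- seq_len(min(ccs_top, nrow(df)))
  if (length(top) > 0L) {
    other_labels <- setdiff(unique(clusters[colnames(fb$A)]), K)
    cl <- clusters[colnames(fb$A)]
    cluster_mask <- vapply(other_labels, function(lbl) cl == lbl,
                           logical(ncol(fb$A)))
    csize <- colSums(cluster_mask)
    # per-gene fraction positive in each non-target cluster
    frac_pos <- (fb$A %*% cluster_mask) / rep(csize, each = nrow(fb$A))
    pair_pos <- fb$A[cand[top, 1L], , drop = FALSE] *
      fb$A[cand[top, 2L], , drop = FALSE]
    frac_pair <- (pair_pos %*% cluster_mask) / rep(csize, each = length(top))
    tn_before <- 100 * (1 - frac_pos[df$lead[top], , drop = FALSE])
    tn_after <- 100 * (1 - frac_pair)
    df$ccs[top] <- rowSums(tn_after - tn_before)
    ccs_rank <- .competition_rank(-df$ccs[top])
    df$ccs_rank <- NA_real_
    df$ccs_rank[top] <- ccs_rank
    df$final_rank <- df$hg_rank
    df$final_rank[top] <- (df$hg_rank[top] + ccs_rank) / 2
  } else {
    df$ccs_rank <- NA_real_
    df$final_rank <- df$hg_rank
  }
  ord <- order(df$final_rank, df$hypergeom_pvalue, df$key, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$key <- NULL
  df
}

.empty_panel_df <- function(size) {
  df <- data.frame(matrix(character(0), 0L, size), stringsAsFactors = FALSE)
  names(df) <- paste0("gene_", seq_len(size))
  df$positives_total <- integer(0)
  df$positives_in_K <- integer(0)
  df$hypergeom_pvalue <- numeric(0)
  df$tp_rate <- numeric(0)
  df$tn_rate <- numeric(0)
  df
}

# Exhaustive triple/quad counting via the Q-matrix construction: Q holds the
# row-wise AND of gene pairs; Q %*% t(A) counts positives for pair+gene
# triples, Q %*% t(Q) for pair+pair quads. Evaluated in pair-row blocks.
.matmul_panels <- function(fb, size, block_size) {
  A <- fb$A
  p <- nrow(A)
  pairs <- .all_combos(p, 2L)
  if (nrow(pairs) == 0L) return(list(cand = matrix(integer(0), 0L, size),
                                     total = integer(0), in_K = integer(0)))
  AK <- A[, fb$inK, drop = FALSE]
  cand_list <- total_list <- inK_list <- list()
  li <- 0L
  for (start in seq(1L, nrow(pairs), by = block_size)) {
    idx <- start:min(start + block_size - 1L, nrow(pairs))
    pb <- pairs[idx, , drop = FALSE]
    Q <- A[pb[, 1L], , drop = FALSE] * A[pb[, 2L], , drop = FALSE]
    QK <- Q[, fb$inK, drop = FALSE]
    if (size == 3L) {
      Tot <- Q %*% t(A)        # block-pairs x genes
      TotK <- QK %*% t(AK)
      # canonical: third gene index > max(pair)
      sel <- which(outer(pb[, 2L], seq_len(p), FUN = "<"), arr.ind = TRUE)
      if (nrow(sel)) {
        li <- li + 1L
        cand_list[[li]] <- cbind(pb[sel[, 1L], , drop = FALSE], sel[, 2L])
        total_list[[li]] <- as.integer(Tot[sel])
        inK_list[[li]] <- as.integer(TotK[sel])
      }
    } else {
      # quads: pair block against every pair whose min index > max(block pair)
      QQ <- Q %*% t(.panel_Q_full(A))
      QQK <- QK %*% t(.panel_Q_full(AK))
      all_pairs <- pairs
      sel <- which(outer(pb[, 2L], all_pairs[, 1L], FUN = "<"), arr.ind = TRUE)
      if (nrow(sel)) {
        li <- li + 1L
        cand_list[[li]] <- cbind(pb[sel[, 1L], , drop = FALSE],
                                 all_pairs[sel[, 2L], , drop = FALSE])
        total_list[[li]] <- as.integer(QQ[sel])
        inK_list[[li]] <- as.integer(QQK[sel])
      }
    }
  }
  list(cand = do.call(rbind, cand_list),
       total = unlist(total_list), in_K = unlist(inK_list))
}

.panel_Q_full <- function(A) {
  pairs <- .all_combos(nrow(A), 2L)
  A[pairs[, 1L], , drop = FALSE] * A[pairs[, 2L], , drop = FALSE]
}

.rank_higher_order <- function(fb, size, candidates, block_size) {
  genes <- rownames(fb$A)
  p <- length(genes)
  if (p < size) return(.empty_panel_df(size))
  if (is.null(candidates)) {
    res <- .matmul_panels(fb, size, block_size)
    cand <- res$cand
    counts <- list(total = res$total, in_K = res$in_K)
  } else {
    cand <- candidates
    counts <- .panel_counts(fb$A, fb$inK, cand, block_size)
  }
  if (is.null(cand) || nrow(cand) == 0L) return(.empty_panel_df(size))
  df <- .score_panels(fb, cand, counts)
  ord <- order(df$hypergeom_pvalue, df$key, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$hg_rank <- .competition_rank(df$hypergeom_pvalue)
  df$final_rank <- df$hg_rank
  rownames(df) <- NULL
  df$key <- NULL
  df
}

#' Rank 3-gene panels
#'
#' Exhaustive counts use the Q-matrix construction (row-wise AND of gene
#' pairs, multiplied against the transposed binary matrix), deduplicated to
#' unique gene triples and ranked by hypergeometric p-value.
#'
#' @inheritParams rank_pairs
#' @export
rank_triples <- function(fb, candidates = NULL, block_size = 2000L) {
  .rank_higher_order(fb, 3L, candidates, block_size)
}

#' Rank 4-gene panels
#'
#' Exhaustive counts use the upper triangle of `Q %*% t(Q)` restricted to
#' disjoint pair splits, deduplicated to unique 4-gene subsets and ranked by
#' hypergeometric p-value.
#'
#' @inheritParams rank_pairs
#' @export
rank_quads <- function(fb, candidates = NULL, block_size = 2000L) {
  .rank_higher_order(fb, 4L, candidates, block_size)
}

#' Enforce output caps on a ranked panel list
#'
#' Greedy top-down pass: a lead gene may appear in at most `plot_cap` plotted
#' panels, and any gene may appear at most `gene_cap` times among emitted
#' panels.
#'
#' @param df Ranked panel data.frame (as returned by the `rank_*` functions).
#' @param plot_cap Maximum plotted appearances per lead gene.
#' @param gene_cap Maximum emitted appearances per gene.
#' @return `df` with logical columns `emit` and `plot` appended.
#' @export
limit_panels <- function(df, plot_cap = 10L, gene_cap = 200L) {
  gene_cols <- grep("^gene_", names(df), value = TRUE)
  emit <- logical(nrow(df))
  plt <- logical(nrow(df))
  gene_count <- new.env(parent = emptyenv())
  lead_count <- new.env(parent = emptyenv())
  cnt <- function(env, k) if (is.null(env[[k]])) 0L else env[[k]]
  for (i in seq_len(nrow(df))) {
    members <- unlist(df[i, gene_cols], use.names = FALSE)
    if (all(vapply(members, function(g) cnt(gene_count, g) < gene_cap,
                   logical(1)))) {
      emit[i] <- TRUE
      for (g in members) gene_count[[g]] <- cnt(gene_count, g) + 1L
      lead <- if ("lead" %in% names(df)) df$lead[i] else members[1L]
      if (cnt(lead_count, lead) < plot_cap) {
        plt[i] <- TRUE
        lead_count[[lead]] <- cnt(lead_count, lead) + 1L
      }
    }
  }
  df$emit <- emit
  df$plot <- plt
  df
}
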