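# XL-mHG threshold test: rank-based enrichment of a cluster at the top of a
# gene's expression ranking, with X/L constraints on the threshold search and
# an exact dynamic-programming p-value.

#' Rank cluster membership by decreasing expression
#'
#' Sorts a per-cell 0/1 cluster-membership vector by decreasing expression,
#' producing the ranked binary vector the XL-mHG test operates on. Ties in
#' expression are broken conservatively by default: within a run of tied
#' values, cells *not* in the cluster precede cells in the cluster, so that
#' tied observations can never inflate the apparent enrichment.
#'
#' @param expression Numeric vector of expression values, one per cell.
#'   Must not contain `NA`/`NaN`.
#' @param membership 0/1 (or logical) vector of the same length; 1 marks cells
#'   in the cluster of interest. Must contain at least one 0 and one 1.
#' @param tie_policy `"conservative"` (default; out-of-cluster cells first
#'   within ties) or `"optimistic"` (in-cluster cells first).
#' @return An object of class `ranked_membership`: a list with `labels`
#'   (0/1 integer vector sorted by decreasing expression), `values` (the
#'   sorted expression values), `n` (number of cells), `m` (cluster size)
#'   and `order` (the permutation applied).
#' @examples
#' rank_membership(c(0, 5, 0, 4), c(0, 1, 0, 1))$labels
#' @export
rank_membership <- function(expression, membership,
                            tie_policy = c("conservative", "optimistic")) {
  tie_policy <- match.arg(tie_policy)
  if (length(expression) != length(membership))
    stop("'expression' and 'membership' must have the same length")
  if (anyNA(expression))
    stop("'expression' contains NA/NaN values")
  membership <- as.integer(as.logical(membership))
  if (anyNA(membership))
    stop("'membership' must be coercible to 0/1")
  m <- sum(membership)
  n <- length(membership)
  if (m == 0L || m == n)
    stop("degenerate membership: need at least one cell in and one cell ",
         "outside the cluster")
  ord <- if (tie_policy == "conservative") {
    order(-expression, membership, method = "radix")
  } else {
    order(-expression, -membership, method = "radix")
  }
  structure(list(labels = membership[ord], values = expression[ord],
                 n = n, m = m, order = ord),
            class = "ranked_membership")
}

#' Hypergeometric tail p-value at a fixed threshold
#'
#' Enrichment of the cluster among the top `t` cells of a ranked membership
#' vector: `P(X >= k_t)` for `X ~ Hypergeometric(n, m, t)`, where `k_t` is the
#' number of in-cluster cells among the top `t`.
#'
#' @param t Threshold index in `[0, n]`; `t = 0` returns 1 (empty top set).
#' @param ranked A [rank_membership()] object.
#' @return The upper-tail hypergeometric probability.
#' @export
hg_tail_pvalue <- function(t, ranked) {
  stopifnot(inherits(ranked, "ranked_membership"))
  if (t < 0 || t > ranked$n) stop("'t' must be in [0, n]")
  if (t == 0) return(1)
  k <- sum(ranked$labels[seq_len(t)])
  stats::phyper(k - 1, ranked$m, ranked$n - ranked$m, t, lower.tail = FALSE)
}

#' Default X and L parameters for a cluster
#'
#' `X = ceiling(0.15 * |K|)` (at least 15% of the cluster must pass the
#' threshold) and `L = min(2 * |K|, n)` (the deepest threshold examined is
#' twice the cluster size).
#'
#' @param cluster_size Size of the cluster of interest, `0 < cluster_size < n`.
#' @param n Total number of cells.
#' @return A list with integer elements `X` and `L`.
#' @examples
#' default_xl(100, 1000)  # X = 15, L = 200
#' @export
default_xl <- function(cluster_size, n) {
  if (cluster_size <= 0) stop("'cluster_size' must be positive")
  if (cluster_size >= n) stop("'cluster_size' must be smaller than 'n'")
  list(X = as.integer(ceiling(0.15 * cluster_size)),
       L = as.integer(min(2 * cluster_size, n)))
}

.check_xl <- function(X, L, n, m) {
  if (X < 0 || X > m) stop("'X' must be in [0, m]")
  if (L < X || L > n) stop("'L' must satisfy X <= L <= n")
}

#' XL-mHG statistic
#'
#' Minimum hypergeometric tail p-value over admissible thresholds
#' `t in [1, L]` with at least `X` in-cluster cells above the threshold.
#' When no threshold is admissible the statistic is 1 with threshold index 0.
#'
#' @param ranked A [rank_membership()] object.
#' @param X Minimum number of in-cluster cells above the threshold.
#' @param L Deepest threshold examined.
#' @return A list with `stat` (the minimum tail probability) and
#'   `threshold_index` (the smallest `t` attaining it; 0 if none admissible).
#' @export
mhg_statistic <- function(ranked, X = 0, L = ranked$n) {
  stopifnot(inherits(ranked, "ranked_membership"))
  n <- ranked$n; m <- ranked$m
  .check_xl(X, L, n, m)
  k <- cumsum(ranked$labels)
  t_all <- seq_len(L)
  adm <- t_all[k[t_all] >= X]
  if (length(adm) == 0L)
    return(list(stat = 1, threshold_index = 0L))
  tails <- stats::phyper(k[adm] - 1, m, n - m, adm, lower.tail = FALSE)
  i <- which.min(tails)
  # extreme enrichment can underflow phyper to 0; keep the statistic in (0, 1]
  list(stat = max(tails[i], .Machine$double.xmin), threshold_index = adm[i])
}

# For each threshold t = 1..L, the smallest count b of in-cluster cells such
# that the hypergeometric tail P(X >= b | n, m, t) is <= s; m + 1 when no
# such b exists. Tail probabilities are monotone decreasing in b, so a
# vectorized bisection over all t at once suffices.
.bmin_grid <- function(s, n, m, L) {
  # tiny relative tolerance: a caller-supplied statistic (e.g. the literal
  # 1/6) may differ from phyper's value in the final bit
  s <- s * (1 + 1e-12)
  t <- seq_len(L)
  hi <- pmin(t, m)
  res <- rep.int(m + 1L, L)
  feasible <- stats::phyper(hi - 1, m, n - m, t, lower.tail = FALSE) <= s
  idx <- which(feasible)
  if (length(idx) == 0L) return(res)
  lo <- rep.int(0L, length(idx))   # tail(t, 0) = 1 > s (s < 1 here)
  hi <- hi[idx]
  ti <- t[idx]
  while (any(hi - lo > 1L)) {
    mid <- (lo + hi) %/% 2L
    ok <- stats::phyper(mid - 1, m, n - m, ti, lower.tail = FALSE) <= s
    hi[ok] <- mid[ok]
    lo[!ok] <- mid[!ok]
  }
  res[idx] <- hi
  res
}

#' Exact XL-mHG p-value (dynamic programming)
#'
#' Probability, under a uniform random arrangement of `m` ones among `n`
#' positions, that the XL-constrained mHG statistic is at most `stat`.
#' Computed by a dynamic program over the (position, ones-seen) lattice:
#' a path is absorbed the first time it enters a lattice cell `(t, b)` with
#' `t <= L`, `b >= X` and hypergeometric tail `<= stat`; the p-value is the
#' total absorbed probability mass. Accumulating absorbed mass (a sum of
#' positive terms) avoids the catastrophic cancellation of `1 - P(avoid)`
#' for highly significant statistics.
#'
#' @param stat The observed XL-mHG statistic in `(0, 1]`.
#' @param n Total number of cells.
#' @param m Number of in-cluster cells.
#' @param X,L Threshold-search constraints (see [mhg_statistic()]).
#' @return The exact p-value in `(0, 1]`.
#' @export
mhg_pvalue <- function(stat, n, m, X = 0, L = n) {
  if (!is.finite(stat) || stat <= 0) stop("'stat' must be in (0, 1]")
  if (m <= 0 || m >= n) stop("need 0 < m < n")
  .check_xl(X, L, n, m)
  if (stat >= 1) return(1)
  block_from <- pmax(.bmin_grid(stat, n, m, L), X)
  b <- 0:m
  zeros <- n - m
  f <- numeric(m + 1L)
  f[1L] <- 1
  captured <- 0
  for (t in seq_len(L)) {
    rem <- n - t + 1
    pone <- (m - b) / rem
    pzero <- (zeros - (t - 1 - b)) / rem
    pzero[pzero < 0] <- 0   # infeasible states carry zero mass anyway
    f <- f * pzero + c(0, (f * pone)[seq_len(m)])
    bf <- block_from[t]
    if (bf <= min(t, m)) {
      ib <- (bf:m) + 1L
      captured <- captured + sum(f[ib])
      f[ib] <- 0
    }
  }
  min(max(captured, .Machine$double.xmin), 1)
}

#' XL-mHG test for one gene
#'
#' Convenience wrapper: ranks membership by decreasing expression, computes
#' the XL-mHG statistic, threshold index, exact p-value and the binarization
#' cutoff. With `X`/`L` omitted, defaults from [default_xl()] are used.
#' A constant expression vector is degenerate: statistic 1, p-value 1,
#' threshold index 0 (no informative threshold exists).
#'
#' The cutoff is the expression value at rank `threshold_index + 1` (the first
#' cell excluded by the threshold); cells are called positive when their
#' expression is strictly greater, which implements the slide-up policy for
#' tied boundary values. When `threshold_index = n` the cutoff is `-Inf`.
#'
#' @inheritParams rank_membership
#' @inheritParams mhg_statistic
#' @return A list with `stat`, `threshold_index`, `pvalue`, `cutoff`,
#'   `n`, `m`, `X`, `L`.
#' @examples
#' xlmhg_test(c(5, 4, 3, 0, 0, 0), c(1, 1, 1, 0, 0, 0), X = 1, L = 6)
#' @export
xlmhg_test <- function(expression, membership, X = NULL, L = NULL,
                       tie_policy = "conservative") {
  membership <- as.integer(as.logical(membership))
  m <- sum(membership)
  n <- length(membership)
  if (is.null(X) || is.null(L)) {
    d <- default_xl(m, n)
    if (is.null(X)) X <- d$X
    if (is.null(L)) L <- d$L
  }
  if (length(unique(expression)) == 1L) {
    return(list(stat = 1, threshold_index = 0L, pvalue = 1,
                cutoff = expression[1L], n = n, m = m, X = X, L = L))
  }
  ranked <- rank_membership(expression, membership, tie_policy = tie_policy)
  st <- mhg_statistic(ranked, X = X, L = L)
  pv <- mhg_pvalue(st$stat, n, m, X = X, L = L)
  t_star <- st$threshold_index
  cutoff <- if (t_star >= n) -Inf else ranked$values[t_star + 1L]
  list(stat = st$stat, threshold_index = t_star, pvalue = pv,
       cutoff = cutoff, n = n, m = m, X = X, L = L)
}
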