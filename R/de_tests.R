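# Comparator statistics for the simulation benchmark: standard DE tests,
# logistic-regression LRT, tree-ensemble importance ranking (via the
# scikit-learn command-line bridge) and the Scaled Sum of Ranks metric.

#' Standard differential-expression test suite for one gene
#'
#' Welch's t-test, the Wilcoxon rank-sum test (normal approximation without
#' continuity correction), the two-sample Kolmogorov-Smirnov test, and the
#' likelihood-ratio test for the logistic regression of cluster membership on
#' expression (statistic `2 * (loglik_full - loglik_null)` against chi-square
#' with 1 df; null model intercept-only). Constant input (overall or within a
#' test's requirements) falls back to p = 1 with a flag.
#'
#' @param expression Numeric vector of expression values.
#' @param membership 0/1 vector of cluster membership (both groups non-empty).
#' @return A list with `pvalues` (named numeric: `welch`, `wilcoxon`, `ks`,
#'   `lrt`) and `flags` (named logical; `TRUE` where a constant-data fallback
#'   was applied).
#' @export
de_test_suite <- function(expression, membership) {
  membership <- as.integer(as.logical(membership))
  if (sum(membership) == 0L || sum(membership) == length(membership))
    stop("both groups must be non-empty")
  xK <- expression[membership == 1L]
  xC <- expression[membership == 0L]
  flags <- c(welch = FALSE, wilcoxon = FALSE, ks = FALSE, lrt = FALSE)
  p <- c(welch = 1, wilcoxon = 1, ks = 1, lrt = 1)

  welch <- tryCatch(stats::t.test(xK, xC, var.equal = FALSE)$p.value,
                    error = function(e) NA_real_)
  if (is.na(welch)) flags["welch"] <- TRUE else p["welch"] <- welch

  if (length(unique(expression)) == 1L) {
    flags["wilcoxon"] <- flags["ks"] <- flags["lrt"] <- TRUE
    return(list(pvalues = p, flags = flags))
  }
  p["wilcoxon"] <- suppressWarnings(
    stats::wilcox.test(xK, xC, exact = FALSE, correct = FALSE)$p.value)
  p["ks"] <- suppressWarnings(stats::ks.test(xK, xC, exact = FALSE)$p.value)
  p["lrt"] <- .logistic_lrt(expression, membership)
  list(pvalues = p, flags = flags)
}

# LRT p-value for cluster ~ sigma(b0 + b1 * x) against the intercept-only
# null, chi-square with 1 df. Uses glm.fit for speed on repeated calls.
.logistic_lrt <- function(x, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial()))
  lr <- fit$null.deviance - fit$deviance
  stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
}

#' Scaled Sum of Ranks
#'
#' `SSR = 2 / (s * (s + 1)) * sum(ranks of the s good markers)` under a
#' method's gene ranking; 1 indicates the optimal ranking (all good markers in
#' the top `s` positions), and the score is invariant to permutations among
#' the good markers.
#'
#' @param ranking Character vector of gene ids, best first.
#' @param good_ids Ids of the true good markers; all must appear in `ranking`.
#' @return A list with `value`, `s` and `ranks`.
#' @export
ssr <- function(ranking, good_ids) {
  ranks <- match(good_ids, ranking)
  if (anyNA(ranks))
    stop("good markers missing from ranking: ",
         paste(utils::head(good_ids[is.na(ranks)], 5), collapse = ", "))
  s <- length(good_ids)
  list(value = 2 / (s * (s + 1)) * sum(ranks), s = s, ranks = ranks)
}

#' Rank genes by tree-ensemble Gini importance
#'
#' Fits a random forest or extra-trees classifier (250 trees, sqrt-features,
#' Gini purity) with the pre-installed Python scikit-learn via a bundled
#' bridge script, and ranks genes by decreasing mean-decrease-Gini importance
#' (ties broken by gene order).
#'
#' @param mat Genes-by-cells numeric matrix.
#' @param membership 0/1 cluster labels per cell.
#' @param method `"rf"` (random forest) or `"xt"` (extra trees).
#' @param n_trees Number of trees.
#' @param seed Integer seed forwarded to the classifier.
#' @param python Python interpreter to invoke.
#' @return Character vector of gene ids, best first.
#' @export
rank_genes_forest <- function(mat, membership, method = c("rf", "xt"),
                              n_trees = 250L, seed = 1L, python = "python") {
  method <- match.arg(method)
  script <- system.file("python", "forest_rank.py", package = "markerpanels")
  if (script == "") stop("bundled forest_rank.py not found")
  td <- tempfile("forest")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  xpath <- file.path(td, "X.csv")
  ypath <- file.path(td, "y.csv")
  opath <- file.path(td, "imp.csv")
  data.table::fwrite(data.table::as.data.table(t(mat)), xpath,
                     col.names = FALSE)
  data.table::fwrite(data.table::data.table(y = as.integer(membership)),
                     ypath, col.names = FALSE)
  status <- system2(python, c(script, xpath, ypath, opath, method,
                              as.integer(n_trees), as.integer(seed)),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(opath))
    stop("forest bridge failed (python exit status ", status, ")")
  imp <- as.numeric(readLines(opath))
  if (length(imp) != nrow(mat)) stop("importance length mismatch")
  rownames(mat)[order(-imp, seq_along(imp), method = "radix")]
}

#' Benchmark single-gene tests over an effect-size or sample-size grid
#'
#' Runs the single-gene simulation engine over a grid of conditions and
#' averages each method's p-value over `runs` seeded replicates. The XL-mHG
#' test uses default X/L parameters for the simulated cluster size.
#'
#' @param engine Passed to [simulate_single_gene()].
#' @param effect_grid Numeric grid of effect sizes (vary effect at fixed `n`).
#' @param n_grid Integer grid of total cell counts (vary `n` at fixed
#'   `effect`); exactly one of `effect_grid` / `n_grid` must be given.
#' @param n,effect The fixed value of the non-varied parameter.
#' @param cluster_fraction Cluster fraction (default 0.1).
#' @param runs Replicates per condition (default 100).
#' @param seed Integer seed for the whole sweep.
#' @param methods Subset of `c("xlmhg", "welch", "wilcoxon", "ks", "lrt")`.
#' @return A data.frame with columns `param`, `value`, `method`, `mean_p`,
#'   `sd_p`, `runs`.
#' @export
benchmark_curves <- function(engine = c("gaussian", "negative_binomial"),
                             effect_grid = NULL, n_grid = NULL,
                             n = 5000L, effect = 1, cluster_fraction = 0.1,
                             runs = 100L, seed = 1L,
                             methods = c("xlmhg", "welch", "wilcoxon",
                                         "ks", "lrt")) {
  engine <- match.arg(engine)
  if (is.null(effect_grid) == is.null(n_grid))
    stop("give exactly one of 'effect_grid' or 'n_grid'")
  grid <- if (!is.null(effect_grid))
    data.frame(param = "effect", value = effect_grid) else
    data.frame(param = "n", value = n_grid)
  set.seed(seed)
  out <- list()
  for (gi in seq_len(nrow(grid))) {
    if (grid$param[gi] == "effect") effect <- grid$value[gi] else
      n <- grid$value[gi]
    pmat <- matrix(NA_real_, runs, length(methods),
                   dimnames = list(NULL, methods))
    for (r in seq_len(runs)) {
      sim <- simulate_single_gene(n, effect, engine = engine,
                                  cluster_fraction = cluster_fraction)
      if ("xlmhg" %in% methods)
        pmat[r, "xlmhg"] <- xlmhg_test(sim$expression, sim$membership)$pvalue
      de <- setdiff(methods, "xlmhg")
      if (length(de) > 0L) {
        suite <- de_test_suite(sim$expression, sim$membership)
        pmat[r, de] <- suite$pvalues[de]
      }
    }
    out[[gi]] <- data.frame(param = grid$param[gi], value = grid$value[gi],
                            method = methods, mean_p = colMeans(pmat),
                            sd_p = apply(pmat, 2, stats::sd), runs = runs,
                            row.names = NULL)
  }
  do.call(rbind, out)
}

#' Benchmark marker-recovery SSR of classifiers on simulated matrices
#'
#' For each replicate, simulates a genes-by-cells matrix with known good
#' markers, ranks the genes with each method and scores the ranking with
#' [ssr()]. XL-mHG ranks by p-value (default X/L), `lrt` by the logistic
#' LRT p-value, `rf`/`xt` by tree-ensemble Gini importance.
#'
#' @param engine Passed to [simulate_matrix()].
#' @param runs Number of replicates (default 20).
#' @param seed Integer seed.
#' @param methods Subset of `c("xlmhg", "lrt", "rf", "xt")`.
#' @param ... Further arguments to [simulate_matrix()].
#' @return A data.frame with columns `run`, `method`, `ssr`.
#' @export
benchmark_matrix_ssr <- function(engine = c("gaussian", "poisson_gamma"),
                                 runs = 20L, seed = 1L,
                                 methods = c("xlmhg", "lrt", "rf", "xt"),
                                 ...) {
  engine <- match.arg(engine)
  set.seed(seed)
  out <- list()
  for (r in seq_len(runs)) {
    sim <- simulate_matrix(engine = engine, ...)
    mat <- sim$expression
    genes <- rownames(mat)
    good <- genes[sim$gene_class == "good"]
    inK <- sim$membership
    for (meth in methods) {
      ranking <- switch(meth,
        xlmhg = {
          pv <- vapply(seq_len(nrow(mat)), function(i)
            xlmhg_test(mat[i, ], inK)$pvalue, numeric(1))
          genes[order(pv, seq_along(pv), method = "radix")]
        },
        lrt = {
          pv <- vapply(seq_len(nrow(mat)), function(i)
            .logistic_lrt(mat[i, ], inK), numeric(1))
          genes[order(pv, seq_along(pv), method = "radix")]
        },
        rf = rank_genes_forest(mat, inK, "rf",
                               seed = sample.int(2^31 - 1, 1)),
        xt = rank_genes_forest(mat, inK, "xt",
                               seed = sample.int(2^31 - 1, 1)),
        stop("unknown method: ", meth))
      out[[length(out) + 1L]] <- data.frame(
        run = r, method = meth, ssr = ssr(ranking, good)$value)
    }
  }
  do.call(rbind, out)
}
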