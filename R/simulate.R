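# Monte Carlo simulation engines for benchmarking marker discovery:
# single-gene Gaussian / negative-binomial draws and matrix-level Gaussian /
# noisy Poisson-Gamma generative models.

#' Simulate one gene across two clusters
#'
#' Gaussian engine: in-cluster cells draw from `Normal(effect, 1)`, background
#' cells from `Normal(0, 5)`. Negative-binomial engine: background counts
#' follow `NB(size = 1, prob = 0.1)` (mean 9) and in-cluster counts follow
#' `NB(size = 5, prob = 0.5)` shifted by `4 + effect` (mean `9 + effect`), so
#' the difference in means is exactly `effect`. The cluster comprises
#' `cluster_fraction` of the `n` cells and comes first in the output order
#' unless `shuffle = TRUE`.
#'
#' @param n Total number of cells.
#' @param effect Difference in means between cluster and background.
#' @param engine `"gaussian"` or `"negative_binomial"`.
#' @param cluster_fraction Fraction of cells in the cluster of interest.
#' @param shuffle Randomly permute the cell order.
#' @param seed Optional integer seed (sets the RNG state).
#' @return A list with `expression` (numeric vector) and `membership`
#'   (0/1 integer vector).
#' @export
simulate_single_gene <- function(n, effect,
                                 engine = c("gaussian", "negative_binomial"),
                                 cluster_fraction = 0.1, shuffle = FALSE,
                                 seed = NULL) {
  engine <- match.arg(engine)
  if (cluster_fraction <= 0 || cluster_fraction >= 1)
    stop("'cluster_fraction' must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- round(cluster_fraction * n)
  if (m < 1L || m >= n) stop("cluster size out of range for n = ", n)
  if (engine == "gaussian") {
    xK <- stats::rnorm(m, mean = effect, sd = 1)
    xC <- stats::rnorm(n - m, mean = 0, sd = 5)
  } else {
    xK <- 4 + effect + stats::rnbinom(m, size = 5, prob = 0.5)
    xC <- stats::rnbinom(n - m, size = 1, prob = 0.1)
  }
  expression <- c(xK, xC)
  membership <- c(rep(1L, m), rep(0L, n - m))
  if (shuffle) {
    ord <- sample.int(n)
    expression <- expression[ord]
    membership <- membership[ord]
  }
  list(expression = expression, membership = membership)
}

#' Poisson-Gamma engine configuration
#'
#' Shape parameters of the per-(gene type, population) Gamma priors on mean
#' expression, the common rate `beta`, and the efficiency-noise half-width
#' `efficiency`. Printed exponent shorthand in the source description is read
#' as powers of two (e.g. good markers in the cluster: `2^5`); all values are
#' free parameters here.
#'
#' @param alpha_good_K,alpha_good_C Gamma shapes for good markers in the
#'   cluster / background.
#' @param alpha_non Shape for non-markers (both populations).
#' @param alpha_poor_in,alpha_poor_out Shapes for poor markers inside their
#'   expressing subset of the cluster and everywhere else.
#' @param beta Gamma rate (all types and populations).
#' @param efficiency Efficiency-noise half-width `e`; per-cell scaling factors
#'   are drawn from `Uniform(1 - e, 1 + e)` and counts are Poisson-resampled.
#' @return A list of class `pg_config`.
#' @export
pg_config <- function(alpha_good_K = 2^5, alpha_good_C = 2^4,
                      alpha_non = 2^4, alpha_poor_in = 2^10,
                      alpha_poor_out = 2^4, beta = 0.1, efficiency = 0.2) {
  stopifnot(alpha_good_K > 0, alpha_good_C > 0, alpha_non > 0,
            alpha_poor_in > 0, alpha_poor_out > 0, beta > 0,
            efficiency >= 0, efficiency < 1)
  structure(list(alpha_good_K = alpha_good_K, alpha_good_C = alpha_good_C,
                 alpha_non = alpha_non, alpha_poor_in = alpha_poor_in,
                 alpha_poor_out = alpha_poor_out, beta = beta,
                 efficiency = efficiency),
            class = "pg_config")
}

#' Simulate a genes-by-cells matrix with known marker structure
#'
#' Two clusters (the cluster of interest holds `cluster_fraction` of the
#' cells) and three gene classes: good markers (`good_frac` of genes,
#' cleanly separating the clusters), poor markers (`poor_frac`; expressed
#' only in a random `poor_cell_frac` subset of cluster cells, e.g. subcluster
#' markers or outliers) and non-markers (the remainder).
#'
#' Gaussian engine: non-markers are `Normal(0, 1)` everywhere; good markers
#' are `Normal(good_mean, 1)` in the cluster and `Normal(0, 1)` outside;
#' poor markers are `Normal(poor_mean, 1)` in their expressing subset and
#' `Normal(0, 1)` elsewhere.
#'
#' Poisson-Gamma engine: for each gene and population a mean is drawn from
#' `Gamma(alpha, beta)`, true counts from `Poisson(mean)`; a per-cell
#' efficiency factor `s_i ~ Uniform(1 - e, 1 + e)` scales the true counts,
#' which are then Poisson-resampled (`Z ~ Poisson(s_i * X)`), emulating
#' efficiency and sampling noise of UMI-based protocols.
#'
#' @param engine `"gaussian"` or `"poisson_gamma"`.
#' @param n Number of cells (default 500).
#' @param p Number of genes (default 1000).
#' @param cluster_fraction Fraction of cells in the cluster of interest.
#' @param good_frac,poor_frac Fractions of good / poor marker genes.
#' @param good_mean,poor_mean Gaussian-engine means (cluster shift for good
#'   markers; expressing-subset mean for poor markers).
#' @param poor_cell_frac Fraction of cluster cells expressing a poor marker.
#' @param pg A [pg_config()] (Poisson-Gamma engine only).
#' @param seed Optional integer seed.
#' @return A list with `expression` (p x n matrix, genes as rows),
#'   `membership` (0/1 per cell), and `gene_class` (factor with levels
#'   `"good"`, `"poor"`, `"non"`).
#' @export
simulate_matrix <- function(engine = c("gaussian", "poisson_gamma"),
                            n = 500L, p = 1000L, cluster_fraction = 0.1,
                            good_frac = 0.05, poor_frac = 0.10,
                            good_mean = 1, poor_mean = 30,
                            poor_cell_frac = 0.10, pg = pg_config(),
                            seed = NULL) {
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  m <- round(cluster_fraction * n)
  n_good <- round(good_frac * p)
  n_poor <- round(poor_frac * p)
  n_non <- p - n_good - n_poor
  stopifnot(m >= 1L, m < n, n_good >= 0L, n_poor >= 0L, n_non >= 0L)
  gene_class <- factor(rep(c("good", "poor", "non"),
                           times = c(n_good, n_poor, n_non)),
                       levels = c("good", "poor", "non"))
  inK <- c(rep(TRUE, m), rep(FALSE, n - m))
  X <- matrix(0, p, n)
  if (engine == "gaussian") {
    for (i in seq_len(p)) {
      base <- stats::rnorm(n, 0, 1)
      if (gene_class[i] == "good") {
        base[inK] <- stats::rnorm(m, good_mean, 1)
      } else if (gene_class[i] == "poor") {
        sub <- sample(which(inK), max(1L, round(poor_cell_frac * m)))
        base[sub] <- stats::rnorm(length(sub), poor_mean, 1)
      }
      X[i, ] <- base
    }
  } else {
    beta <- pg$beta
    for (i in seq_len(p)) {
      if (gene_class[i] == "good") {
        muK <- stats::rgamma(1, shape = pg$alpha_good_K, rate = beta)
        muC <- stats::rgamma(1, shape = pg$alpha_good_C, rate = beta)
        X[i, inK] <- stats::rpois(m, muK)
        X[i, !inK] <- stats::rpois(n - m, muC)
      } else if (gene_class[i] == "poor") {
        sub <- sample(which(inK), max(1L, round(poor_cell_frac * m)))
        mu_in <- stats::rgamma(1, shape = pg$alpha_poor_in, rate = beta)
        mu_out <- stats::rgamma(1, shape = pg$alpha_poor_out, rate = beta)
        out <- setdiff(seq_len(n), sub)
        X[i, sub] <- stats::rpois(length(sub), mu_in)
        X[i, out] <- stats::rpois(length(out), mu_out)
      } else {
        mu <- stats::rgamma(1, shape = pg$alpha_non, rate = beta)
        X[i, ] <- stats::rpois(n, mu)
      }
    }
    s <- stats::runif(n, 1 - pg$efficiency, 1 + pg$efficiency)
    X <- matrix(stats::rpois(p * n, t(t(X) * s)), p, n)
  }
  dimnames(X) <- list(sprintf("gene%04d", seq_len(p)),
                      sprintf("cell%04d", seq_len(n)))
  list(expression = X, membership = as.integer(inK), gene_class = gene_class)
}
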