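# Per-cluster orchestration: one independent marker-discovery run per
# cluster, ranked tables written to a per-cluster directory tree.

.singles_columns <- c("gene", "rank", "xlmhg_pvalue", "threshold_index",
                      "cutoff", "tp_rate", "tn_rate", "log2_fc",
                      "pvalue_rank", "fc_rank")

.panel_columns <- function(df, pairs = FALSE) {
  cols <- c(grep("^gene_", names(df), value = TRUE),
            "hypergeom_pvalue", "tp_rate", "tn_rate")
  if (pairs) cols <- c(cols, "ccs")
  c(cols, "final_rank")
}

#' Run marker discovery for every cluster
#'
#' For each cluster in the assignment table: adds negation tracks, computes
#' XL-mHG statistics and the cluster-specific binarization, writes the three
#' single-gene tables under `singles/`, and (for requested panel sizes)
#' ranked pair/triple/quad tables under `pairs/`, `triples/`, `quads/`.
#' Clusters of size 1 are skipped with a warning. A `run.log` records
#' parameters and package/R versions. No normalization is applied
#' internally; normalization and clustering are the caller's responsibility.
#'
#' @param config A [run_config()], or arguments to build one.
#' @param inputs Optional pre-loaded [load_inputs()] result (for programmatic
#'   use; otherwise inputs are read from the configured paths).
#' @return Invisibly, a named list of per-cluster result lists (`singles`,
#'   `pairs`, `triples`, `quads` as requested).
#' @export
run_all_clusters <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg) writeLines(paste0(format(Sys.time(),
                                                "%Y-%m-%d %H:%M:%S "), msg),
                                  log_con)
  log(sprintf("markerpanels %s on R %s.%s",
              as.character(utils::packageVersion("markerpanels")),
              R.version$major, R.version$minor))
  log("input matrix is used as provided; no internal normalization")
  log(sprintf("panel sizes: %s; heuristic: %s (core %d); seed: %d",
              paste(config$panel_sizes, collapse = ","),
              config$heuristic, config$core_size, config$seed))
  if (is.null(inputs)) inputs <- load_inputs(config, log = log)
  mat <- add_negations(inputs$matrix)
  clusters <- inputs$clusters
  labels <- sort(unique(clusters))
  results <- list()
  for (K in labels) {
    m <- sum(clusters == K)
    if (m < 2L) {
      warning("skipping cluster '", K, "' of size ", m)
      log(sprintf("skipped cluster %s (size %d)", K, m))
      next
    }
    log(sprintf("cluster %s: %d cells", K, m))
    cdir <- file.path(config$output_dir, paste0("cluster_", K))
    gs <- gene_stats(mat, clusters, K, X = config$X, L = config$L)
    res <- list()
    if (1L %in% config$panel_sizes) {
      tabs <- rank_single_genes(gs)
      sdir <- file.path(cdir, "singles")
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      .write_tsv(.format_singles(tabs$ranked),
                 file.path(sdir, "ranked_all.tsv"))
      .write_tsv(.format_singles(tabs$ranked_positive),
                 file.path(sdir, "ranked_positive.tsv"))
      .write_tsv(tabs$full, file.path(sdir, "full_statistics.tsv"))
      res$singles <- tabs
      if (config$plot && !is.null(inputs$coords))
        .plot_top_singles(tabs$ranked, mat, gs, inputs$coords, sdir)
    }
    panel_sizes <- setdiff(config$panel_sizes, 1L)
    if (length(panel_sizes) > 0L) {
      fb <- filter_binary(gs)
      core <- .heuristic_core(fb, config$core_size)
      for (size in panel_sizes) {
        dname <- c("2" = "pairs", "3" = "triples", "4" = "quads")[
          as.character(size)]
        pdir <- file.path(cdir, dname)
        dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
        cand <- if (config$heuristic)
          heuristic_candidates(core, nrow(fb$A), size) else NULL
        tab <- switch(as.character(size),
                      "2" = rank_pairs(fb, clusters, K, candidates = cand),
                      "3" = rank_triples(fb, candidates = cand),
                      "4" = rank_quads(fb, candidates = cand))
        tab <- limit_panels(tab)
        .write_tsv(tab[tab$emit, .panel_columns(tab, pairs = size == 2L),
                       drop = FALSE],
                   file.path(pdir, "ranked_panels.tsv"))
        res[[dname]] <- tab
      }
    }
    results[[as.character(K)]] <- res
  }
  log("done")
  invisible(results)
}

.format_singles <- function(df) {
  if (nrow(df) == 0L)
    return(stats::setNames(
      data.frame(matrix(nrow = 0L, ncol = length(.singles_columns))),
      .singles_columns))
  df[, .singles_columns, drop = FALSE]
}

# Core set for the heuristic: top-N retained genes by single-gene XL-mHG
# p-value (ties broken by gene id for determinism).
.heuristic_core <- function(fb, core_size) {
  ord <- order(fb$single_pvalue, names(fb$single_pvalue), method = "radix")
  utils::head(ord, core_size)
}

# Minimal binarization scatter plots for the top-ranked genes.
.plot_top_singles <- function(ranked, mat, gs, coords, dir, top = 10L) {
  shared <- intersect(colnames(mat), rownames(coords))
  if (length(shared) == 0L) return(invisible(NULL))
  xy <- coords[shared, , drop = FALSE]
  for (g in utils::head(ranked$gene, top)) {
    png_path <- file.path(dir, paste0("plot_", gsub("[^A-Za-z0-9_.-]", "_", g),
                                      ".png"))
    grDevices::png(png_path, width = 600, height = 300)
    graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
    expr <- mat[g, shared]
    pos <- gs$binary[g, shared]
    cols <- grDevices::gray(1 - (expr - min(expr)) /
                              max(max(expr) - min(expr), 1e-12))
    graphics::plot(xy$x, xy$y, col = cols, pch = 16, main = g)
    graphics::plot(xy$x, xy$y, col = ifelse(pos, "red", "grey"), pch = 16,
                   main = "binarized")
    grDevices::dev.off()
  }
  invisible(NULL)
}
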