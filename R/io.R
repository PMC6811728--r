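# File input: dense TSV/CSV or MatrixMarket sparse expression matrices,
# two-column cluster tables, optional 2-D coordinates and gene lists.

#' Read a genes-by-cells expression matrix
#'
#' Dense TSV/CSV (first column = gene ids, header = cell ids) or
#' MatrixMarket sparse triplet (`.mtx`) with companion row-id and column-id
#' text files (one id per line). Input is accepted genes-as-rows by default;
#' set `genes_as_rows = FALSE` to transpose a cells-by-genes file.
#'
#' @param path Matrix file.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @param row_ids,col_ids Id files for `mtx` input (defaults:
#'   `<path>.rownames` / `<path>.colnames`).
#' @param genes_as_rows Whether rows of the file are genes.
#' @return Numeric matrix, genes as rows.
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "csv",
                                                    "mtx"),
                                   row_ids = paste0(path, ".rownames"),
                                   col_ids = paste0(path, ".colnames"),
                                   genes_as_rows = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    if (!file.exists(row_ids) || !file.exists(col_ids))
      stop("mtx input needs row/column id files: ", row_ids, ", ", col_ids)
    mat <- as.matrix(Matrix::readMM(path))
    rownames(mat) <- readLines(row_ids)
    colnames(mat) <- readLines(col_ids)
  } else {
    dt <- data.table::fread(path, sep = if (format == "csv") "," else "\t",
                            header = TRUE)
    ids <- as.character(dt[[1L]])
    mat <- as.matrix(dt[, -1L, drop = FALSE])
    rownames(mat) <- ids
    storage.mode(mat) <- "double"
  }
  if (!genes_as_rows) mat <- t(mat)
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(mat))) stop("duplicate cell ids in ", path)
  mat
}

#' Read a cell-to-cluster assignment table
#'
#' Two-column TSV/CSV (cell id, cluster label), header optional.
#'
#' @param path Table file.
#' @return Named character vector mapping cell id to cluster label.
#' @export
read_cluster_assignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = "auto")
  if (ncol(dt) < 2L) stop("cluster table needs two columns (cell, cluster)")
  cl <- as.character(dt[[2L]])
  names(cl) <- as.character(dt[[1L]])
  if (anyDuplicated(names(cl))) stop("duplicate cell ids in cluster table")
  cl
}

#' Read per-cell 2-D visualization coordinates
#'
#' Three-column table (cell id, x, y).
#'
#' @param path Table file.
#' @return Data.frame with rownames = cell ids and columns `x`, `y`.
#' @export
read_coordinates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = "auto")
  if (ncol(dt) < 3L) stop("coordinate table needs columns (cell, x, y)")
  out <- data.frame(x = as.numeric(dt[[2L]]), y = as.numeric(dt[[3L]]))
  rownames(out) <- as.character(dt[[1L]])
  out
}

#' Assemble and validate a run configuration
#'
#' @param matrix_path Expression matrix file.
#' @param clusters_path Cluster assignment table.
#' @param output_dir Output directory (created if absent).
#' @param coords_path Optional coordinates file (enables plots).
#' @param gene_list_path Optional file with one gene id per line; the search
#'   is restricted to these genes.
#' @param X,L Optional XL-mHG overrides (defaults are per-cluster).
#' @param panel_sizes Subset of 1:4.
#' @param heuristic Use the heuristic candidate search for panels.
#' @param core_size Heuristic core size `N` (default 50).
#' @param seed Integer seed recorded in the run log.
#' @param plot Produce binarization scatter plots when coordinates are given.
#' @param genes_as_rows Orientation of the matrix file.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(matrix_path, clusters_path, output_dir,
                       coords_path = NULL, gene_list_path = NULL,
                       X = NULL, L = NULL, panel_sizes = c(1L, 2L),
                       heuristic = FALSE, core_size = 50L, seed = 1L,
                       plot = FALSE, genes_as_rows = TRUE) {
  panel_sizes <- sort(unique(as.integer(panel_sizes)))
  if (length(panel_sizes) == 0L || !all(panel_sizes %in% 1:4))
    stop("'panel_sizes' must be a non-empty subset of 1:4")
  if (core_size < 1L) stop("'core_size' must be >= 1")
  structure(list(matrix_path = matrix_path, clusters_path = clusters_path,
                 output_dir = output_dir, coords_path = coords_path,
                 gene_list_path = gene_list_path, X = X, L = L,
                 panel_sizes = panel_sizes, heuristic = heuristic,
                 core_size = as.integer(core_size), seed = as.integer(seed),
                 plot = plot, genes_as_rows = genes_as_rows),
            class = "run_config")
}

#' Load and reconcile all pipeline inputs
#'
#' Reads the expression matrix, cluster table and optional coordinates/gene
#' list; restricts the matrix to the gene list when given; drops (with a
#' logged count) cells missing from either the matrix or the cluster table.
#'
#' @param config A [run_config()].
#' @param log A function taking a message string (default `message`).
#' @return A list with `matrix`, `clusters`, `coords` (or `NULL`),
#'   `dropped_cells`.
#' @export
load_inputs <- function(config, log = message) {
  mat <- read_expression_matrix(config$matrix_path,
                                genes_as_rows = config$genes_as_rows)
  clusters <- read_cluster_assignments(config$clusters_path)
  shared <- intersect(colnames(mat), names(clusters))
  if (length(shared) == 0L)
    stop("no overlapping cell ids between matrix and cluster table")
  dropped <- (ncol(mat) - length(shared)) +
    (length(clusters) - length(shared))
  if (dropped > 0L)
    log(sprintf("dropped %d cells absent from matrix or cluster table",
                dropped))
  mat <- mat[, shared, drop = FALSE]
  clusters <- clusters[shared]
  if (!is.null(config$gene_list_path)) {
    wanted <- readLines(config$gene_list_path)
    wanted <- wanted[nzchar(wanted)]
    keep <- intersect(rownames(mat), wanted)
    if (length(keep) == 0L) stop("gene list shares no genes with the matrix")
    log(sprintf("restricted to %d of %d genes from the gene list",
                length(keep), nrow(mat)))
    mat <- mat[keep, , drop = FALSE]
  }
  coords <- if (!is.null(config$coords_path))
    read_coordinates(config$coords_path) else NULL
  list(matrix = mat, clusters = clusters, coords = coords,
       dropped_cells = dropped)
}

.write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
}
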