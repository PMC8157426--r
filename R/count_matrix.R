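#' Construct a cell-by-gene count matrix container
#'
#' The canonical in-memory dataset holds raw counts with cells in rows and
#' genes in columns, plus optional ground-truth cluster labels (one per cell).
#' All readers normalize to this orientation.
#'
#' @param counts Numeric matrix, cells in rows, genes in columns. Entries must
#'   be non-negative. Raw integer counts are expected; real-valued (already
#'   normalized) matrices are accepted with a warning so that individual
#'   preprocessing steps can be switched off for them.
#' @param cell_ids Character vector of unique cell identifiers (default: row
#'   names, or `cell_1..cell_n` when absent).
#' @param gene_ids Character vector of unique gene identifiers (default:
#'   column names, or `gene_1..gene_d` when absent).
#' @param labels Optional vector of ground-truth cluster labels, length equal
#'   to the number of cells.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `cell_ids`, `gene_ids`, `labels`.
#' @examples
#' cm <- count_matrix(matrix(rpois(12, 5), 3, 4))
#' dim(cm)
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL,
                         labels = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  d <- ncol(counts)
  if (n < 2L || d < 2L) {
    stop("count_matrix needs at least 2 cells and 2 genes, got ",
         n, " x ", d, call. = FALSE)
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts contain missing or non-finite entries", call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at cell ", bad[1L], ", gene ", bad[2L], call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    warning("counts contain non-integer values; treating them as ",
            "already-normalized expression", call. = FALSE)
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(counts)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(counts)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(d))
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  stopifnot(length(cell_ids) == n, length(gene_ids) == d)
  if (anyDuplicated(cell_ids)) stop("cell_ids are not unique", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene_ids are not unique", call. = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != n) {
      stop("labels must have one entry per cell (", n, "), got ",
           length(labels), call. = FALSE)
    }
    labels <- as.character(labels)
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(
    list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
         labels = labels),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes", sep = "")
  if (!is.null(x$labels)) {
    cat("; labels: ", length(unique(x$labels)), " groups", sep = "")
  }
  sparsity <- mean(x$counts == 0)
  cat(sprintf("; sparsity %.1f%%\n", 100 * sparsity))
  invisible(x)
}

#' Subset a count matrix by cells and/or genes
#'
#' @param x A [count_matrix()].
#' @param cells,genes Index vectors (integer, logical or character).
#' @param ... Unused.
#' @return A `count_matrix` restricted to the selected cells and genes.
#' @export
subset.count_matrix <- function(x, cells = NULL, genes = NULL, ...) {
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  if (is.character(cells)) cells <- match(cells, x$cell_ids)
  if (is.character(genes)) genes <- match(genes, x$gene_ids)
  count_matrix(
    x$counts[cells, genes, drop = FALSE],
    cell_ids = x$cell_ids[cells],
    gene_ids = x$gene_ids[genes],
    labels = if (!is.null(x$labels)) x$labels[cells]
  )
}

#' Tidy a count matrix into a long tibble
#'
#' One row per stored (cell, gene) pair with a nonzero count, mirroring the
#' triplet layout of sparse on-disk formats.
#'
#' @param x A [count_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `cell_id`, `gene_id`, `count`.
#' @export
tidy.count_matrix <- function(x, ...) {
  idx <- which(x$counts != 0, arr.ind = TRUE)
  tibble::tibble(
    cell_id = x$cell_ids[idx[, 1L]],
    gene_id = x$gene_ids[idx[, 2L]],
    count = x$counts[idx]
  )
}

#' One-row summary of a count matrix
#'
#' @param x A [count_matrix()].
#' @param ... Unused.
#' @return A tibble with `n_cells`, `n_genes`, `sparsity`, `median_total`,
#'   `n_groups` (NA without labels).
#' @export
glance.count_matrix <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$counts),
    n_genes = ncol(x$counts),
    sparsity = mean(x$counts == 0),
    median_total = stats::median(rowSums(x$counts)),
    n_groups = if (is.null(x$labels)) NA_integer_
               else length(unique(x$labels))
  )
}
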