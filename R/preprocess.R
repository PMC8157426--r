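#' Preprocessing configuration
#'
#' Bundles the knobs of the four-step recipe applied before representation
#' learning: gene filtering, median library-size normalization, natural-log
#' transform, dispersion-ranked highly-variable-gene (HVG) selection and
#' per-gene scaling.
#'
#' @param min_cells_expressed Genes with a nonzero count in fewer than this
#'   many cells are discarded (default 2, i.e. genes expressed in one cell or
#'   less are dropped).
#' @param n_top_genes Number of top variable genes to keep, or `"all"`
#'   (default 500).
#' @param log Apply the log1p transform (default TRUE).
#' @param scale Scale each gene to zero mean / unit variance (default TRUE).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(min_cells_expressed = 2L, n_top_genes = 500L,
                              log = TRUE, scale = TRUE) {
  if (!identical(n_top_genes, "all")) {
    n_top_genes <- as.integer(n_top_genes)
    if (is.na(n_top_genes) || n_top_genes < 2L) {
      stop("n_top_genes must be >= 2 or \"all\"", call. = FALSE)
    }
  }
  min_cells_expressed <- as.integer(min_cells_expressed)
  stopifnot(min_cells_expressed >= 0L)
  structure(
    list(min_cells_expressed = min_cells_expressed,
         n_top_genes = n_top_genes, log = isTRUE(log), scale = isTRUE(scale)),
    class = "preprocess_config"
  )
}

#' Discard genes expressed in too few cells
#'
#' "Expressed" means a strictly positive count. With the default threshold of
#' 2 cells, genes expressed in only one cell or less are removed.
#'
#' @param cm A [count_matrix()].
#' @param min_cells_expressed Minimum number of cells with a nonzero count.
#' @return A filtered [count_matrix()]; the cell set is unchanged.
#' @export
filter_genes <- function(cm, min_cells_expressed = 2L) {
  stopifnot(inherits(cm, "count_matrix"))
  n_expressed <- colSums(cm$counts > 0)
  keep <- n_expressed >= min_cells_expressed
  if (!any(keep)) {
    stop("gene filter removed all ", ncol(cm$counts), " genes", call. = FALSE)
  }
  if (all(keep)) return(cm)
  subset(cm, genes = which(keep))
}

#' Median library-size normalization
#'
#' Divides each cell's counts by its total and multiplies by the median of
#' all cells' totals, so every cell ends with the same total expression.
#'
#' @param cm A [count_matrix()] or a bare numeric matrix (cells x genes).
#' @return A list with `values` (the normalized matrix) and
#'   `size_factor_target` (the median total count).
#' @export
normalize_library_size <- function(cm) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)[1L]
    id <- rownames(m)[bad]
    stop("cell ", if (is.null(id)) bad else id,
         " has zero total count; cannot normalize", call. = FALSE)
  }
  med <- stats::median(totals)
  list(values = m * (med / totals), size_factor_target = med)
}

#' Natural-log transform with pseudo-count
#'
#' Entrywise `ln(1 + x)`; zeros map to zero. The pseudo-count resolves the
#' zeros that raw `ln` cannot handle while keeping the transform monotone.
#'
#' @param m Non-negative numeric matrix.
#' @return The transformed matrix.
#' @export
log_transform <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("log_transform requires non-negative entries",
                       call. = FALSE)
  log1p(m)
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Seurat-flavour ranking: per-gene dispersion is variance/mean; genes are
#' binned into 20 equal-frequency bins of mean expression and the dispersion
#' is z-scored within each bin, making lowly- and highly-expressed genes
#' comparable. Degenerate bins (a single gene, or zero spread) fall back to
#' the raw dispersion. Ties break by higher mean, then input order.
#'
#' @param m Real matrix (cells x genes), typically log-normalized.
#' @param gene_ids Gene identifiers (default: column names).
#' @param n_top Number of genes to keep (must be <= ncol(m)).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return A list with `values` (cells x n_top matrix, columns in rank
#'   order), `selected_genes`, and `dispersion` (the full ranking tibble).
#' @export
select_hvg <- function(m, gene_ids = colnames(m), n_top, n_bins = 20L) {
  m <- as.matrix(m)
  d <- ncol(m)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(d))
  if (n_top > d) {
    stop("n_top (", n_top, ") exceeds the number of genes (", d, ")",
         call. = FALSE)
  }
  mu <- colMeans(m)
  v <- apply(m, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency bins of the mean; fewer bins when few distinct values
  breaks <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(breaks) > 2L) {
    cut(mu, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, d)
  }
  norm_disp <- disp
  for (b in unique(bin)) {
    idx <- which(bin == b)
    if (length(idx) < 2L) next  # single-gene bin: keep raw dispersion
    s <- stats::sd(disp[idx])
    if (!is.finite(s) || s == 0) next  # zero-spread bin: keep raw dispersion
    norm_disp[idx] <- (disp[idx] - mean(disp[idx])) / s
  }
  ord <- order(-norm_disp, -mu, seq_len(d))
  sel <- ord[seq_len(n_top)]
  list(
    values = m[, sel, drop = FALSE],
    selected_genes = gene_ids[sel],
    dispersion = tibble::tibble(
      gene_id = gene_ids, mean = mu, dispersion = disp,
      dispersion_norm = norm_disp, rank = match(seq_len(d), ord)
    )
  )
}

#' Scale each gene to zero mean and unit variance
#'
#' Constant genes become all-zero columns rather than NaN. The per-gene means
#' and standard deviations are recorded so the transform is invertible.
#'
#' @param m Real matrix (cells x genes).
#' @return A list with `values`, `per_gene_mean`, `per_gene_std`.
#' @export
scale_genes <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("scale_genes requires finite entries",
                               call. = FALSE)
  mu <- colMeans(m)
  s <- apply(m, 2L, stats::sd)
  s_safe <- ifelse(s > 0, s, 1)
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, s_safe, "/")
  out[, s == 0] <- 0
  list(values = out, per_gene_mean = mu, per_gene_std = s)
}

#' Run the full preprocessing recipe
#'
#' Composition, in order: gene filter, median library-size normalization,
#' log1p transform (optional), HVG selection, per-gene scaling (optional).
#' Deterministic: identical input and config give bit-identical output.
#'
#' @param cm A [count_matrix()].
#' @param cfg A [preprocess_config()].
#' @return A `preprocessed_matrix`: list with `values` (cells x d'), `
#'   selected_genes` (in dispersion rank order), `per_gene_mean`,
#'   `per_gene_std`, `size_factor_target`, `cell_ids`, `labels`.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 300,
#'   group_sizes = rep(20, 2), seed = 1))
#' pm <- preprocess(sim$cm, preprocess_config(n_top_genes = 50))
#' dim(pm$values)
#' @export
preprocess <- function(cm, cfg = preprocess_config()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(cfg, "preprocess_config"))
  cm <- filter_genes(cm, cfg$min_cells_expressed)
  norm <- normalize_library_size(cm)
  m <- norm$values
  if (cfg$log) m <- log_transform(m)
  n_top <- if (identical(cfg$n_top_genes, "all")) ncol(m)
           else min(cfg$n_top_genes, ncol(m))
  hvg <- select_hvg(m, gene_ids = cm$gene_ids, n_top = n_top)
  m <- hvg$values
  if (cfg$scale) {
    sc <- scale_genes(m)
  } else {
    sc <- list(values = m,
               per_gene_mean = rep(0, ncol(m)),
               per_gene_std = rep(1, ncol(m)))
  }
  structure(
    list(values = sc$values,
         selected_genes = hvg$selected_genes,
         per_gene_mean = sc$per_gene_mean,
         per_gene_std = sc$per_gene_std,
         size_factor_target = norm$size_factor_target,
         cell_ids = cm$cell_ids,
         labels = cm$labels,
         config = cfg),
    class = "preprocessed_matrix"
  )
}

#' @export
print.preprocessed_matrix <- function(x, ...) {
  cat("<preprocessed_matrix> ", nrow(x$values), " cells x ", ncol(x$values),
      " genes (median total ", signif(x$size_factor_target, 4), ")\n",
      sep = "")
  invisible(x)
}
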