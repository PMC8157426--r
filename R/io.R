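#' Read a count matrix from CSV/TSV, MatrixMarket MTX, or H5AD
#'
#' All formats are normalized to the canonical cells-by-genes orientation.
#' For `csv` the first column holds row names and the header holds column
#' names; a `.tsv`/`.txt` extension switches the delimiter to tab. For `mtx`
#' the triplet file may be accompanied by sidecar name files
#' `<path>.rownames` and `<path>.colnames` (one name per line); missing names
#' are synthesized. For `h5ad` the main matrix is taken as counts unless a
#' `counts` layer exists, which is preferred; reading shells out to the
#' `python` interpreter on the PATH (needs the `anndata` module).
#'
#' @param path Path to the file.
#' @param format One of `"csv"`, `"mtx"`, `"h5ad"`. Default guesses from the
#'   file extension.
#' @param orientation `"cells_by_genes"` (default) or `"genes_by_cells"`,
#'   describing the on-disk layout. The returned object is always
#'   cells-by-genes.
#' @param labels Optional path to a labels CSV (columns `cell_id`, `label`),
#'   matched to cells by id.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path,
                        format = c("guess", "csv", "mtx", "h5ad"),
                        orientation = c("cells_by_genes", "genes_by_cells"),
                        labels = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = , tsv = , txt = "csv",
      mtx = "mtx",
      h5ad = "h5ad",
      stop("cannot guess format from extension '", ext,
           "'; pass format explicitly", call. = FALSE)
    )
  }
  res <- switch(format,
    csv = read_counts_csv(path),
    mtx = read_counts_mtx(path),
    h5ad = read_counts_h5ad(path)
  )
  m <- res$m
  if (orientation == "genes_by_cells") m <- t(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("cell_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("gene_", seq_len(ncol(m)))
  lab <- res$labels
  if (!is.null(labels)) {
    lab_tbl <- read_labels(labels)
    idx <- match(rownames(m), lab_tbl$cell_id)
    if (anyNA(idx)) {
      stop("labels file is missing ", sum(is.na(idx)), " cell ids",
           call. = FALSE)
    }
    lab <- lab_tbl$label[idx]
  }
  count_matrix(m, labels = lab)
}

read_counts_csv <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                      check.names = FALSE, comment.char = ""),
    error = function(e) {
      stop("failed to parse ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1L)))[1L]
    stop("non-numeric column '", colnames(df)[bad], "' in ", path,
         call. = FALSE)
  }
  list(m = m, labels = NULL)
}

read_counts_mtx <- function(path) {
  m <- tryCatch(
    as.matrix(Matrix::readMM(path)),
    error = function(e) {
      stop("failed to parse MatrixMarket file ", path, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  rn_path <- paste0(path, ".rownames")
  cn_path <- paste0(path, ".colnames")
  if (file.exists(rn_path)) {
    rn <- readLines(rn_path)
    if (length(rn) != nrow(m)) {
      stop("sidecar ", rn_path, " has ", length(rn), " names for ",
           nrow(m), " rows", call. = FALSE)
    }
    rownames(m) <- rn
  }
  if (file.exists(cn_path)) {
    cn <- readLines(cn_path)
    if (length(cn) != ncol(m)) {
      stop("sidecar ", cn_path, " has ", length(cn), " names for ",
           ncol(m), " columns", call. = FALSE)
    }
    colnames(m) <- cn
  }
  list(m = m, labels = NULL)
}

# H5AD via the python anndata module: exports the matrix (preferring a
# "counts" layer), obs/var names, and any obs column named "label"/"labels"/
# "cell_type" to a temporary directory, then reads those text files.
read_counts_h5ad <- function(path) {
  py <- Sys.which("python")
  if (py == "") {
    stop("reading h5ad requires a 'python' interpreter with the anndata ",
         "module on the PATH", call. = FALSE)
  }
  out_dir <- tempfile("h5ad_export_")
  dir.create(out_dir)
  on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
  script <- c(
    "import sys",
    "import numpy as np",
    "import scipy.sparse as sp",
    "import scipy.io as sio",
    "import anndata as ad",
    "path, out = sys.argv[1], sys.argv[2]",
    "a = ad.read_h5ad(path)",
    "x = a.layers['counts'] if 'counts' in a.layers else a.X",
    "x = sp.csr_matrix(x) if not sp.issparse(x) else x.tocsr()",
    "sio.mmwrite(out + '/m.mtx', x)",
    "open(out + '/rows.txt', 'w').write('\\n'.join(map(str, a.obs_names)) + '\\n')",
    "open(out + '/cols.txt', 'w').write('\\n'.join(map(str, a.var_names)) + '\\n')",
    "for col in ('label', 'labels', 'cell_type', 'Group'):",
    "    if col in a.obs.columns:",
    "        open(out + '/labels.txt', 'w').write('\\n'.join(map(str, a.obs[col])) + '\\n')",
    "        break"
  )
  script_file <- file.path(out_dir, "export.py")
  writeLines(script, script_file)
  status <- system2(py, c(script_file, shQuote(path), shQuote(out_dir)),
                    stdout = file.path(out_dir, "out.log"),
                    stderr = file.path(out_dir, "err.log"))
  if (status != 0L) {
    stop("h5ad export failed: ",
         paste(readLines(file.path(out_dir, "err.log")), collapse = "\n"),
         call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(file.path(out_dir, "m.mtx")))
  rownames(m) <- readLines(file.path(out_dir, "rows.txt"))
  colnames(m) <- readLines(file.path(out_dir, "cols.txt"))
  lab_file <- file.path(out_dir, "labels.txt")
  labels <- if (file.exists(lab_file)) readLines(lab_file) else NULL
  list(m = m, labels = labels)
}

#' Read a per-cell label file
#'
#' @param path CSV with columns `cell_id` and `label` (header required), or a
#'   single unnamed column of labels.
#' @return A tibble with columns `cell_id` (possibly NA) and `label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("cell_id", "label") %in% colnames(df))) {
    tibble::tibble(cell_id = as.character(df$cell_id),
                   label = as.character(df$label))
  } else if (ncol(df) == 1L) {
    tibble::tibble(cell_id = NA_character_, label = as.character(df[[1L]]))
  } else {
    stop("labels file must have columns cell_id,label or a single column",
         call. = FALSE)
  }
}

#' Write a count matrix to CSV or MatrixMarket MTX
#'
#' CSV output is cells-by-genes with cell ids as row names. MTX output writes
#' the sparse triplet file plus `<path>.rownames`/`<path>.colnames` sidecars.
#' When labels are present they are written to `<path stem>_labels.csv`.
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @param format `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("csv", "mtx")) {
  stopifnot(inherits(cm, "count_matrix"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(cm$counts), path)
  } else {
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
    writeLines(cm$cell_ids, paste0(path, ".rownames"))
    writeLines(cm$gene_ids, paste0(path, ".colnames"))
  }
  if (!is.null(cm$labels)) {
    lab_path <- paste0(tools::file_path_sans_ext(path), "_labels.csv")
    utils::write.csv(
      data.frame(cell_id = cm$cell_ids, label = cm$labels),
      lab_path, row.names = FALSE
    )
  }
  invisible(path)
}

#' Write a partition (cluster assignment) to a two-column CSV
#'
#' @param partition A [partition()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "partition"))
  if (length(partition$labels) == 0L) {
    stop("refusing to write an empty partition", call. = FALSE)
  }
  utils::write.csv(
    data.frame(cell_id = partition$cell_ids, cluster = partition$labels),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a partition written by [write_partition()]
#'
#' @param path CSV with columns `cell_id`, `cluster`.
#' @return A [partition()].
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path)
  lab <- as.integer(df$cluster)
  # written partitions are already canonically labelled; keep them verbatim
  structure(
    list(labels = lab, K = length(unique(lab)),
         cell_ids = as.character(df$cell_id), method = "file",
         params = list(path = path)),
    class = "partition"
  )
}

#' Write a cell embedding to CSV
#'
#' First column `cell_id`, then one numeric column per embedding dimension
#' (`e1..eK`). Values round-trip within 1e-12.
#'
#' @param embedding An [embedding()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "embedding"))
  if (any(!is.finite(embedding$z))) {
    stop("embedding contains non-finite values", call. = FALSE)
  }
  df <- data.frame(cell_id = embedding$cell_ids, embedding$z,
                   check.names = FALSE)
  colnames(df) <- c("cell_id", paste0("e", seq_len(ncol(embedding$z))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path CSV path.
#' @return An [embedding()].
#' @export
read_embedding <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  z <- as.matrix(df[, -1L, drop = FALSE])
  embedding(z, cell_ids = as.character(df[[1L]]))
}
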