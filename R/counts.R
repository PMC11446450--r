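#' Construct a cells-by-genes count matrix container
#'
#' Bundles a non-negative integer count matrix (cells in rows, genes in
#' columns) with cell/gene identifiers and optional per-cell ground-truth
#' class labels. All simulation, preprocessing and IO functions in the
#' package operate on this container.
#'
#' @param counts Numeric matrix of non-negative integer counts, cells in rows.
#' @param cell_ids Character vector of cell identifiers (defaults to rownames).
#' @param gene_ids Character vector of gene identifiers (defaults to colnames).
#' @param labels Optional per-cell class labels (character or factor). When
#'   present every class must have at least two member cells.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix), `cell_ids`, `gene_ids`, and `labels` (or `NULL`).
#' @examples
#' m <- matrix(c(0, 1, 2, 3, 4, 5), nrow = 3)
#' cm <- count_matrix(m, labels = c("a", "a", "a"))
#' dim(cm)
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts), labels = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(!is.finite(counts))) abort("counts contain non-finite values")
  if (any(counts < 0)) abort("counts contain negative entries")
  if (any(counts != round(counts))) abort("counts must be integers")
  n <- nrow(counts)
  g <- ncol(counts)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%04d", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%04d", seq_len(g))
  if (length(cell_ids) != n) {
    abort(sprintf("cell_ids has %d entries for %d cells", length(cell_ids), n))
  }
  if (length(gene_ids) != g) {
    abort(sprintf("gene_ids has %d entries for %d genes", length(gene_ids), g))
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) {
      abort(sprintf("labels has %d entries for %d cells", length(labels), n))
    }
    tab <- table(labels)
    if (any(tab < 2)) {
      abort(paste0(
        "every class must have >= 2 cells; singleton class(es): ",
        paste(names(tab)[tab < 2], collapse = ", ")
      ))
    }
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- NULL
  structure(
    list(counts = counts, cell_ids = as.character(cell_ids),
         gene_ids = as.character(gene_ids), labels = labels),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d cells x %d genes%s\n",
    nrow(x$counts), ncol(x$counts),
    if (is.null(x$labels)) "" else
      sprintf(", %d classes", length(unique(x$labels)))
  ))
  invisible(x)
}

#' Read a count matrix from disk
#'
#' Two on-disk layouts are supported. `format = "mtx"`: `path` is a directory
#' holding `matrix.mtx` (MatrixMarket, genes in rows, cells in columns),
#' `genes.tsv` (one gene id per line) and `cells.tsv` (cell id and, optionally,
#' a second label column). `format = "tsv"`: `path` is a single dense
#' tab-separated file whose header row holds gene ids and whose first column
#' holds cell ids; labels, if any, live in a companion `<stem>_labels.tsv`
#' (columns cell_id, label) next to the matrix file.
#'
#' @param path Directory (mtx) or file (tsv) to read.
#' @param format `"mtx"` or `"tsv"`.
#' @return A [count_matrix()].
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx_file <- file.path(path, "matrix.mtx")
    genes_file <- file.path(path, "genes.tsv")
    cells_file <- file.path(path, "cells.tsv")
    for (f in c(mtx_file, genes_file, cells_file)) {
      if (!file.exists(f)) abort(paste0("missing file: ", f))
    }
    m <- Matrix::readMM(mtx_file)
    if (any(m@x < 0)) {
      bad <- which(m@x < 0)[1]
      abort(sprintf("matrix.mtx contains a negative entry (stored value %d)", bad))
    }
    genes <- readr::read_tsv(genes_file, col_names = FALSE,
                             show_col_types = FALSE, progress = FALSE)
    cells <- readr::read_tsv(cells_file, col_names = FALSE,
                             show_col_types = FALSE, progress = FALSE)
    if (nrow(genes) != nrow(m)) {
      abort(sprintf("genes.tsv has %d lines but matrix.mtx has %d gene rows",
                    nrow(genes), nrow(m)))
    }
    if (nrow(cells) != ncol(m)) {
      abort(sprintf("cells.tsv has %d lines but matrix.mtx has %d cell columns",
                    nrow(cells), ncol(m)))
    }
    labels <- if (ncol(cells) >= 2) as.character(cells[[2]]) else NULL
    count_matrix(t(as.matrix(m)), cell_ids = as.character(cells[[1]]),
                 gene_ids = as.character(genes[[1]]), labels = labels)
  } else {
    if (!file.exists(path)) abort(paste0("missing file: ", path))
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    cell_ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    labels_file <- paste0(sub("\\.tsv$", "", path), "_labels.tsv")
    labels <- NULL
    if (file.exists(labels_file)) {
      lt <- readr::read_tsv(labels_file, show_col_types = FALSE, progress = FALSE)
      if (nrow(lt) != nrow(m)) {
        abort(sprintf("label file %s has %d rows but matrix has %d cells",
                      labels_file, nrow(lt), nrow(m)))
      }
      labels <- as.character(lt[[2]])
    }
    count_matrix(m, cell_ids = cell_ids, gene_ids = colnames(m), labels = labels)
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]; a write-then-read round trip reproduces counts,
#' identifiers and labels exactly.
#'
#' @param x A [count_matrix()].
#' @param path Directory (mtx) or file path (tsv) to write.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "count_matrix"))
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(x$counts), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble(gene_id = x$gene_ids),
                     file.path(path, "genes.tsv"), col_names = FALSE)
    cells <- if (is.null(x$labels)) tibble(cell_id = x$cell_ids) else
      tibble(cell_id = x$cell_ids, label = x$labels)
    readr::write_tsv(cells, file.path(path, "cells.tsv"), col_names = FALSE)
  } else {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    tab <- as_tibble(as.data.frame(x$counts))
    names(tab) <- x$gene_ids
    tab <- dplyr::bind_cols(tibble(cell_id = x$cell_ids), tab)
    readr::write_tsv(tab, path)
    if (!is.null(x$labels)) {
      readr::write_tsv(tibble(cell_id = x$cell_ids, label = x$labels),
                       paste0(sub("\\.tsv$", "", path), "_labels.tsv"))
    }
  }
  invisible(path)
}
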