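#' Single-cell dataset container
#'
#' A light genes x cells container: a sparse count matrix plus per-cell
#' metadata. Metadata columns used downstream, when present: `sample`,
#' `tissue`, `response`, `batch`, `cluster`, `pseudotime`, `trb_cdr3`.
#'
#' @param counts genes x cells matrix of non-negative integers (dense or
#'   `Matrix` sparse); rownames are gene symbols, colnames are cell
#'   barcodes.
#' @param cell_meta Data frame with one row per cell, rownames matching the
#'   column names of `counts` (or in the same order).
#' @return A `CellDataset`.
#' @export
cell_dataset <- function(counts, cell_meta = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(cell_meta))
    cell_meta <- data.frame(row.names = colnames(counts))
  if (nrow(cell_meta) != ncol(counts))
    stop("cell_meta rows must match count matrix columns", call. = FALSE)
  rownames(cell_meta) <- colnames(counts)
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "CellDataset")
}

#' @export
print.CellDataset <- function(x, ...) {
  cat(sprintf("CellDataset: %d genes x %d cells; metadata: %s\n",
              nrow(x$counts), ncol(x$counts),
              if (ncol(x$cell_meta)) paste(names(x$cell_meta), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' @export
dim.CellDataset <- function(x) dim(x$counts)

#' Subset a cell dataset
#'
#' @param x A `CellDataset`.
#' @param genes,cells Index vectors (logical, integer or names).
#' @return The subset `CellDataset`.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "CellDataset"))
  if (is.null(genes)) genes <- seq_len(nrow(x$counts))
  if (is.null(cells)) cells <- seq_len(ncol(x$counts))
  cell_dataset(x$counts[genes, cells, drop = FALSE],
               x$cell_meta[cells, , drop = FALSE])
}

#' Read a cell dataset from matrix-market triplet files
#'
#' Expects `matrix.mtx` (genes x cells), `genes.tsv` (one symbol per line),
#' `barcodes.tsv` (one barcode per line) and optionally `cell_meta.csv`
#' (row-per-cell metadata keyed by a `barcode` column or by row order)
#' under `dir`.
#'
#' @param dir Directory containing the files.
#' @return A `CellDataset`.
#' @export
read_cell_dataset <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(genes, cells)
  meta_path <- file.path(dir, "cell_meta.csv")
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    if ("barcode" %in% names(meta)) {
      rownames(meta) <- meta$barcode
      meta$barcode <- NULL
      meta <- meta[cells, , drop = FALSE]
    }
  }
  cell_dataset(m, meta)
}

#' Write a cell dataset as matrix-market triplet files
#'
#' @param x A `CellDataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_dataset <- function(x, dir) {
  stopifnot(inherits(x, "CellDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  meta <- cbind(barcode = colnames(x$counts), x$cell_meta)
  utils::write.csv(meta, file.path(dir, "cell_meta.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Library-size normalized log2 expression
#'
#' Per-cell counts scaled to a common library size, then `log2(x + 1)`.
#' The pipeline default input to density gating, scoring and pseudotime
#' fitting.
#'
#' @param x A `CellDataset` or genes x cells matrix.
#' @param scale_factor Target library size (default 1e4).
#' @return A dense genes x cells matrix of log2 normalized expression.
#' @export
lognorm_counts <- function(x, scale_factor = 1e4) {
  m <- if (inherits(x, "CellDataset")) x$counts else x
  libs <- Matrix::colSums(m)
  libs[libs == 0] <- 1
  out <- as.matrix(m %*% Matrix::Diagonal(x = scale_factor / libs))
  dimnames(out) <- dimnames(m)
  log2(out + 1)
}
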