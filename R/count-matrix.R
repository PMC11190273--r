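#' Gene-by-cell UMI count container
#'
#' Bundles a sparse gene x cell UMI count matrix with a cell metadata tibble
#' (one row per barcode) and a gene metadata tibble (one row per gene). This
#' is the universal input of the pipeline: QC, normalization, marker calling
#' and differential expression all consume it.
#'
#' @param counts A gene x cell matrix of non-negative integer UMI counts;
#'   coerced to [Matrix::dgCMatrix-class]. Row names are gene ids, column
#'   names are cell barcodes.
#' @param cells A data frame with one row per column of `counts`. Must
#'   contain a `barcode` column matching `colnames(counts)`; typically also
#'   `donor`, `diagnosis`, `sex`, `apoe4`, `batch`, `cluster`.
#' @param genes A data frame with one row per row of `counts`. Must contain
#'   a `gene` column matching `rownames(counts)`; typically also a logical
#'   `mito` flag and optionally `protein_coding`.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `cells` and `genes`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 1), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' cm <- count_matrix(m)
#' dim(cm)
count_matrix <- function(counts, cells = NULL, genes = NULL) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(
    counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene row names and barcode column names")
  }
  if (any(counts@x < 0)) stop("UMI counts must be non-negative")
  if (is.null(cells)) cells <- tibble::tibble(barcode = colnames(counts))
  if (is.null(genes)) genes <- tibble::tibble(gene = rownames(counts))
  cells <- tibble::as_tibble(cells)
  genes <- tibble::as_tibble(genes)
  if (!"barcode" %in% names(cells)) stop("`cells` needs a `barcode` column")
  if (!"gene" %in% names(genes)) stop("`genes` needs a `gene` column")
  if (!identical(cells$barcode, colnames(counts))) {
    stop("`cells$barcode` must match colnames(counts) in order")
  }
  if (!identical(genes$gene, rownames(counts))) {
    stop("`genes$gene` must match rownames(counts) in order")
  }
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat("cell metadata: ", paste(names(x$cells), collapse = ", "), "\n")
  cat("gene metadata: ", paste(names(x$genes), collapse = ", "), "\n")
  invisible(x)
}

# Subset a count_matrix by gene and/or cell index, keeping metadata aligned.
subset_count_matrix <- function(cm, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- seq_len(nrow(cm$counts))
  if (is.null(cells)) cells <- seq_len(ncol(cm$counts))
  count_matrix(cm$counts[genes, cells, drop = FALSE],
               cm$cells[cells, , drop = FALSE],
               cm$genes[genes, , drop = FALSE])
}

#' Write a count matrix to a 10x-style directory
#'
#' Writes `matrix.mtx` (1-based coordinate Matrix Market), `genes.tsv`,
#' `barcodes.tsv` and `cell_metadata.tsv`.
#'
#' @param cm A [count_matrix()].
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(cm$genes, file.path(dir, "genes.tsv"))
  readr::write_lines(cm$cells$barcode, file.path(dir, "barcodes.tsv"))
  readr::write_tsv(cm$cells, file.path(dir, "cell_metadata.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` and (optionally) `cell_metadata.tsv`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           show_col_types = FALSE)
  barcodes <- readr::read_lines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "cell_metadata.tsv")
  cells <- if (file.exists(meta_path)) {
    readr::read_tsv(meta_path, show_col_types = FALSE)
  } else {
    tibble::tibble(barcode = barcodes)
  }
  rownames(m) <- genes$gene
  colnames(m) <- barcodes
  count_matrix(m, cells, genes)
}
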