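#' Read an expression matrix from TSV
#'
#' Expects genes in rows and cells in columns: the first column holds gene
#' identifiers and the header row holds cell identifiers (FPKM-like
#' non-negative values).
#'
#' @param path Path to a tab-separated file.
#' @return A named numeric matrix, genes x cells.
#' @export
read_expression_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(ncol(tbl) >= 2L, "expression TSV needs a gene-id column plus at least one cell column")
  genes <- as.character(tbl[[1L]])
  mat <- as.matrix(tbl[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  validate_expression_matrix(mat, arg = path)
}

#' Write an expression matrix to TSV
#'
#' @param mat Named numeric matrix, genes x cells.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  validate_expression_matrix(mat)
  tbl <- tibble::as_tibble(mat, rownames = "gene_id")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read an expression matrix in MatrixMarket triplet form
#'
#' Reads `matrix.mtx` together with the 1-based row (gene) and column (cell)
#' name side files, following the common genes.tsv / barcodes.tsv layout.
#'
#' @param mtx Path to the `.mtx` file.
#' @param genes Path to a one-column (or first-column) gene id file.
#' @param cells Path to a one-column cell id file.
#' @return A dense named numeric matrix, genes x cells.
#' @export
read_expression_mtx <- function(mtx, genes, cells) {
  m <- as.matrix(Matrix::readMM(mtx))
  gene_ids <- readr::read_tsv(genes, col_names = FALSE, show_col_types = FALSE, progress = FALSE)[[1L]]
  cell_ids <- readr::read_tsv(cells, col_names = FALSE, show_col_types = FALSE, progress = FALSE)[[1L]]
  assert_that(length(gene_ids) == nrow(m), "gene id file does not match matrix rows")
  assert_that(length(cell_ids) == ncol(m), "cell id file does not match matrix columns")
  dimnames(m) <- list(as.character(gene_ids), as.character(cell_ids))
  storage.mode(m) <- "double"
  validate_expression_matrix(m, arg = mtx)
}

#' Write an expression matrix in MatrixMarket triplet form
#'
#' @inheritParams write_expression_tsv
#' @param dir Output directory; `matrix.mtx`, `genes.tsv` and `barcodes.tsv`
#'   are written inside it.
#' @return `dir`, invisibly.
#' @export
write_expression_mtx <- function(mat, dir) {
  validate_expression_matrix(mat)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(x = rownames(mat)), file.path(dir, "genes.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(tibble::tibble(x = colnames(mat)), file.path(dir, "barcodes.tsv"),
                   col_names = FALSE, progress = FALSE)
  invisible(dir)
}
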