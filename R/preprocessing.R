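#' Filter cells by housekeeping-gene expression
#'
#' A cell is removed only if *all* listed housekeeping genes are unexpressed
#' (value <= 0) in that cell: "expressing neither" housekeeping gene marks a
#' failed library. Column order of the surviving cells is preserved.
#'
#' @param mat Named numeric matrix, genes x cells, FPKM-like non-negative.
#' @param housekeeping Character vector of housekeeping gene ids; every id
#'   must be present in the matrix.
#' @return The filtered matrix. The ids of removed cells are attached as
#'   attribute `"removed_cells"` (also retrievable with [removed_cells()]).
#' @export
filter_cells <- function(mat, housekeeping = c("ACTB", "GAPDH")) {
  validate_expression_matrix(mat)
  validate_nonnegative(mat)
  assert_that(length(housekeeping) >= 1L, "`housekeeping` must name at least one gene")
  missing <- setdiff(housekeeping, rownames(mat))
  if (length(missing) > 0L) {
    stop_ptdyn(sprintf("housekeeping gene(s) absent from matrix: %s",
                       paste(missing, collapse = ", ")))
  }
  hk <- mat[housekeeping, , drop = FALSE]
  failed <- colSums(hk > 0) == 0L
  if (all(failed)) stop_ptdyn("all cells failed the housekeeping filter")
  out <- mat[, !failed, drop = FALSE]
  attr(out, "removed_cells") <- colnames(mat)[failed]
  out
}

#' @rdname filter_cells
#' @param x A matrix returned by [filter_cells()].
#' @export
removed_cells <- function(x) attr(x, "removed_cells") %||% character(0L)

#' Quantile-normalize an expression matrix
#'
#' Forces an identical value distribution on every cell: each column's sorted
#' values are replaced by the across-column mean of sorted columns, mapped
#' back by rank, so every column becomes an exact permutation of the same
#' reference vector. A group of tied entries collectively receives the
#' reference values of its rank span (deterministically, in order of
#' appearance), keeping the distributions of all cells exactly identical even
#' when tie patterns differ (e.g. dropout zeros). Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param mat Named numeric matrix, genes x cells, with >= 2 cells.
#' @return The normalized matrix (same dimnames).
#' @export
quantile_normalize <- function(mat) {
  validate_expression_matrix(mat)
  assert_that(ncol(mat) >= 2L, "quantile normalization needs at least 2 cells")
  out <- limma::normalizeQuantiles(mat, ties = FALSE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-gene z-scores of log2 expression
#'
#' Converts FPKM-like values to `log2(value + 1)` and standardizes each gene
#' across cells (mean 0, unit sample standard deviation). Genes with zero
#' variance carry no ordering information and are dropped with a warning;
#' their ids are attached as attribute `"dropped_genes"`.
#'
#' @param mat Named numeric matrix, genes x cells, with >= 2 cells.
#' @return The standardized matrix (possibly fewer rows).
#' @export
log_standardize <- function(mat) {
  validate_expression_matrix(mat)
  validate_nonnegative(mat)
  assert_that(ncol(mat) >= 2L, "standardization needs at least 2 cells")
  lg <- log2(mat + 1)
  mu <- rowMeans(lg)
  sdev <- apply(lg, 1L, stats::sd)
  zero_var <- sdev == 0
  if (any(zero_var)) {
    rlang::warn(sprintf("dropping %d zero-variance gene(s): %s%s",
                        sum(zero_var),
                        paste(utils::head(rownames(mat)[zero_var], 5L), collapse = ", "),
                        if (sum(zero_var) > 5L) ", ..." else ""))
  }
  out <- (lg[!zero_var, , drop = FALSE] - mu[!zero_var]) / sdev[!zero_var]
  assert_that(nrow(out) > 0L, "all genes have zero variance; nothing left to standardize")
  attr(out, "dropped_genes") <- rownames(mat)[zero_var]
  out
}

#' Standard preprocessing chain
#'
#' Housekeeping filter followed by quantile normalization (a hook point for an
#' externally cell-cycle-corrected matrix exists between the two: pass that
#' matrix directly to this function with `filter = FALSE`).
#'
#' @inheritParams filter_cells
#' @param filter If `FALSE`, skip the housekeeping filter (e.g. for matrices
#'   already filtered and corrected upstream).
#' @return The filtered, quantile-normalized matrix; `"removed_cells"`
#'   attribute as in [filter_cells()].
#' @export
preprocess_matrix <- function(mat, housekeeping = c("ACTB", "GAPDH"), filter = TRUE) {
  removed <- character(0L)
  if (filter) {
    mat <- filter_cells(mat, housekeeping)
    removed <- removed_cells(mat)
  }
  out <- quantile_normalize(mat)
  attr(out, "removed_cells") <- removed
  out
}
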