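#' Gene set Z-score (GSZ) for one gene set
#'
#' For each cell, the GSZ compares the summed gene-level scores of the set
#' against the mean and variance expected when drawing a same-size set at
#' random (without replacement) from all genes in that cell. With per-cell
#' gene scores `x_g`, set size `m` and `N` genes in total:
#' `S = sum(x_g, g in set)`, `E = m * mu_c`,
#' `V = m * sigma_c^2 * (N - m) / (N - 1)` (finite-population correction,
#' `sigma_c^2` the population variance over genes in the cell), and
#' `GSZ = (S - E) / sqrt(V + lambda)`.
#'
#' Gene-level scores are expected to be per-gene z-scores of log2 expression
#' across cells (see [log_standardize()]), which calibrates the GSZ null
#' towards mean 0 / variance 1. Set members absent from the matrix are
#' dropped with a warning (case-sensitive symbol matching).
#'
#' @param standardized Named numeric matrix of gene-level scores,
#'   genes x cells.
#' @param genes Character vector of gene ids defining the set.
#' @param lambda Additive variance regularizer, >= 0 (default 0).
#' @return A tibble with columns `cell_id` and `gsz`, plus attributes
#'   `set_size` (genes used), `unmatched` (set members not in the matrix) and
#'   `lambda`.
#' @export
gsz_score <- function(standardized, genes, lambda = 0) {
  validate_expression_matrix(standardized, arg = "standardized")
  assert_that(is.character(genes) && length(genes) > 0L, "`genes` must be a character vector")
  assert_that(is_scalar_num(lambda) && lambda >= 0, "`lambda` must be >= 0")
  genes <- unique(genes)
  hit <- intersect(genes, rownames(standardized))
  if (length(hit) == 0L) stop_ptdyn("no gene of the set is present in the matrix")
  unmatched <- setdiff(genes, hit)
  if (length(unmatched) > 0L) {
    rlang::warn(sprintf("%d of %d set member(s) absent from the matrix and dropped",
                        length(unmatched), length(genes)))
  }
  m <- length(hit)
  N <- nrow(standardized)
  if (m == N && lambda == 0) {
    stop_ptdyn("the set covers every gene in the matrix: null variance is zero (use lambda > 0)")
  }
  S <- colSums(standardized[hit, , drop = FALSE])
  mu <- colMeans(standardized)
  sigma2 <- colMeans(standardized^2) - mu^2  # population variance over genes
  V <- m * sigma2 * (N - m) / (N - 1)
  gsz <- (S - m * mu) / sqrt(V + lambda)
  assert_that(all(is.finite(gsz)), "GSZ is not finite for every cell (degenerate gene scores?)")
  out <- tibble::tibble(cell_id = colnames(standardized), gsz = unname(gsz))
  attr(out, "set_size") <- m
  attr(out, "unmatched") <- unmatched
  attr(out, "lambda") <- lambda
  out
}

#' GSZ for every set of a collection
#'
#' @inheritParams gsz_score
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @return A long tibble with columns `set`, `cell_id`, `gsz`.
#' @export
score_gene_sets <- function(standardized, sets, lambda = 0) {
  assert_that(is.list(sets) && length(sets) > 0L && !is.null(names(sets)),
              "`sets` must be a non-empty named list")
  purrr::imap(sets, function(genes, nm) {
    dplyr::mutate(gsz_score(standardized, genes, lambda = lambda), set = nm, .before = 1L)
  }) %>%
    dplyr::bind_rows()
}

#' Reshape a long GSZ table to cells x sets
#'
#' @param gsz_long Tibble with columns `set`, `cell_id`, `gsz`.
#' @return A wide tibble, one row per cell, one column per set.
#' @export
gsz_table <- function(gsz_long) {
  assert_that(all(c("set", "cell_id", "gsz") %in% names(gsz_long)),
              "`gsz_long` needs columns set, cell_id, gsz")
  tidyr::pivot_wider(gsz_long, names_from = "set", values_from = "gsz")
}
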