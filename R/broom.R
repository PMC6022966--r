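#' Tidy a pseudotime result
#'
#' @param x A `pseudotime_result`.
#' @param ... Unused.
#' @return A tibble with one row per cell: `cell_id`, `pt`, `rank`.
#' @exportS3Method generics::tidy
tidy.pseudotime_result <- function(x, ...) {
  dplyr::mutate(dplyr::arrange(x$pt, .data$pt), rank = dplyr::row_number())
}

#' One-row summary of a pseudotime result
#'
#' @param x A `pseudotime_result`.
#' @param ... Unused.
#' @return A one-row tibble with the ensemble parameters, start cell,
#'   orientation flag and cell count.
#' @exportS3Method generics::glance
glance.pseudotime_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$pt), start_cell = x$start_cell, oriented = x$oriented,
    k = x$params$k, l = x$params$l, n_graphs = x$params$n_graphs,
    metric = x$params$metric, seed = x$params$seed
  )
}

#' Tidy an association run
#'
#' @param x A `pt_association` table from [rank_targets()].
#' @param ... Unused.
#' @return The association table as a plain tibble.
#' @exportS3Method generics::tidy
tidy.pt_association <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of an association run
#'
#' @param x A `pt_association` table.
#' @param ... Unused.
#' @return A one-row tibble: number of targets, significant counts per
#'   direction at the stored FDR threshold, spline df.
#' @exportS3Method generics::glance
glance.pt_association <- function(x, ...) {
  thr <- attr(x, "fdr_threshold") %||% 0.05
  sig <- significant_targets(x, thr)
  tibble::tibble(
    n_targets = nrow(x),
    n_correlated = nrow(sig$correlated),
    n_anti_correlated = nrow(sig$anti_correlated),
    fdr_threshold = thr,
    spline_df = attr(x, "spline_df") %||% NA_integer_
  )
}
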