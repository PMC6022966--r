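#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select bind_rows group_by ungroup
#'   summarise left_join desc n
#' @importFrom purrr map map_dbl map_chr imap
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# single place for the pipe so the package works without magrittr attached
#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

stop_ptdyn <- function(msg, class = "ptdyn_error") {
  rlang::abort(msg, class = class)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_ptdyn(msg)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Validate the genes x cells container used throughout the pipeline.
validate_expression_matrix <- function(mat, arg = "matrix") {
  assert_that(is.matrix(mat) && is.numeric(mat),
              sprintf("`%s` must be a numeric matrix (genes in rows, cells in columns)", arg))
  assert_that(!is.null(rownames(mat)) && !is.null(colnames(mat)),
              sprintf("`%s` must have gene row names and cell column names", arg))
  assert_that(!anyDuplicated(rownames(mat)), sprintf("`%s` has duplicated gene ids", arg))
  assert_that(!anyDuplicated(colnames(mat)), sprintf("`%s` has duplicated cell ids", arg))
  assert_that(!anyNA(mat), sprintf("`%s` contains missing values", arg))
  invisible(mat)
}

validate_nonnegative <- function(mat, arg = "matrix") {
  assert_that(all(mat >= 0), sprintf("`%s` contains negative expression values", arg))
  invisible(mat)
}

# Deterministic Spearman correlation used in several places.
spearman <- function(x, y) stats::cor(x, y, method = "spearman")
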