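#' Spline likelihood-ratio test for pseudotime dependence
#'
#' Compares a Gaussian additive model of the values on a natural cubic spline
#' basis of pseudotime (with `spline_df` degrees of freedom plus intercept)
#' against the intercept-only model. The statistic is twice the log-likelihood
#' difference; the p-value is taken from a chi-square distribution with
#' `spline_df` degrees of freedom. Constant values give `lr_stat = 0`,
#' `p = 1` by definition (the models coincide).
#'
#' @param pt Per-cell pseudotimes.
#' @param values Per-cell response values (GSZ or standardized log
#'   expression), same length.
#' @param spline_df Spline degrees of freedom (default 3).
#' @return A list with `lr_stat`, `df` and `p`.
#' @export
gam_lrt <- function(pt, values, spline_df = 3L) {
  assert_that(is.numeric(pt) && is.numeric(values) && length(pt) == length(values),
              "`pt` and `values` must be numeric vectors of equal length")
  assert_that(is_count(spline_df), "`spline_df` must be a positive integer")
  n <- length(pt)
  assert_that(n >= spline_df + 5L,
              sprintf("need at least spline_df + 5 = %d cells", spline_df + 5L))
  if (stats::var(values) == 0) {
    return(list(lr_stat = 0, df = as.integer(spline_df), p = 1))
  }
  basis <- splines::ns(pt, df = spline_df)
  full <- stats::lm(values ~ basis)
  reduced <- stats::lm(values ~ 1)
  lr <- max(0, 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(reduced))))
  list(lr_stat = lr, df = as.integer(spline_df),
       p = stats::pchisq(lr, df = spline_df, lower.tail = FALSE))
}

#' Rank genes or gene sets by pseudotime dependence
#'
#' Runs [gam_lrt()] on every target, applies Benjamini-Hochberg FDR
#' adjustment across the run, assigns a direction from the sign of the
#' Spearman correlation with pseudotime (ties count as `correlated`) and
#' sorts by ascending FDR, then by descending likelihood-ratio statistic.
#'
#' @param x Targets-by-cells input: a named numeric matrix (rows = targets,
#'   e.g. genes of a standardized matrix), or a long GSZ tibble with columns
#'   `set`, `cell_id`, `gsz`.
#' @param pt_tbl Tibble with columns `cell_id`, `pt`, or a numeric vector of
#'   pseudotimes in the column order of the matrix.
#' @param spline_df Spline degrees of freedom (default 3).
#' @param fdr_threshold Threshold stored with the result and used by
#'   [significant_targets()] (default 0.05).
#' @return A `pt_association` tibble: `target`, `lr_stat`, `df`, `p`, `fdr`,
#'   `direction`.
#' @export
rank_targets <- function(x, pt_tbl, spline_df = 3L, fdr_threshold = 0.05) {
  if (is.data.frame(x)) {
    assert_that(all(c("set", "cell_id", "gsz") %in% names(x)),
                "data-frame input needs columns set, cell_id, gsz")
    wide <- tidyr::pivot_wider(x, names_from = "cell_id", values_from = "gsz")
    m <- as.matrix(wide[, -1L, drop = FALSE])
    rownames(m) <- wide$set
    x <- m
  }
  assert_that(is.matrix(x) && !is.null(rownames(x)), "`x` must be a named targets x cells matrix")
  pt <- if (is.data.frame(pt_tbl)) {
    assert_that(all(colnames(x) %in% pt_tbl$cell_id), "pseudotime missing for some cells")
    stats::setNames(pt_tbl$pt, pt_tbl$cell_id)[colnames(x)]
  } else {
    assert_that(length(pt_tbl) == ncol(x), "`pt_tbl` length must match number of cells")
    pt_tbl
  }
  assert_that(nrow(x) >= 1L, "at least one target is required")

  res <- purrr::map(rownames(x), function(tg) {
    v <- x[tg, ]
    lrt <- gam_lrt(pt, v, spline_df = spline_df)
    rho <- if (stats::var(v) == 0) 0 else spearman(v, pt)
    tibble::tibble(target = tg, lr_stat = lrt$lr_stat, df = lrt$df, p = lrt$p,
                   direction = if (rho >= 0) "correlated" else "anti-correlated")
  }) %>%
    dplyr::bind_rows() %>%
    dplyr::mutate(fdr = stats::p.adjust(.data$p, method = "BH"), .after = "p") %>%
    dplyr::arrange(.data$fdr, dplyr::desc(abs(.data$lr_stat)))
  attr(res, "spline_df") <- as.integer(spline_df)
  attr(res, "fdr_threshold") <- fdr_threshold
  class(res) <- c("pt_association", class(res))
  res
}

#' Significant targets split by direction
#'
#' @param association A [rank_targets()] result.
#' @param fdr_threshold FDR cut-off; defaults to the one stored with the run.
#' @return Named list of two tibbles, `correlated` and `anti_correlated`.
#' @export
significant_targets <- function(association, fdr_threshold = NULL) {
  fdr_threshold <- fdr_threshold %||% attr(association, "fdr_threshold") %||% 0.05
  hits <- dplyr::filter(tibble::as_tibble(association), .data$fdr <= fdr_threshold)
  list(
    correlated = dplyr::filter(hits, .data$direction == "correlated"),
    anti_correlated = dplyr::filter(hits, .data$direction == "anti-correlated")
  )
}
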