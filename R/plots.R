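#' Plot pseudotime against cell rank
#'
#' The pseudotime-versus-rank curve makes an initial slow component visible
#' as a flat early segment; an optional [detect_slow_component()] result adds
#' the fitted breakpoint as a dashed line.
#'
#' @param object A `pseudotime_result`.
#' @param breakpoint Optional `breakpoint_result` to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pseudotime_result <- function(object, breakpoint = NULL, ...) {
  d <- tidy(object)
  d$rank_norm <- (d$rank - 1) / (nrow(d) - 1)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank_norm, y = .data$pt)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::labs(x = "normalized cell rank", y = "pseudotime",
                  title = sprintf("Pseudotime vs rank (start: %s)", object$start_cell)) +
    ggplot2::theme_minimal()
  if (!is.null(breakpoint) && is.finite(breakpoint$pt_star[1L])) {
    p <- p + ggplot2::geom_hline(yintercept = breakpoint$pt_star[1L], linetype = "dashed")
  }
  p
}

#' Plot signature profiles along pseudotime
#'
#' @param profiles A long `signature_profile` tibble (see
#'   [profile_signatures()]).
#' @param relative Plot the relative activity (default) or the raw smoothed
#'   GSZ.
#' @return A ggplot object, one coloured curve per signature.
#' @export
plot_profiles <- function(profiles, relative = TRUE) {
  ycol <- if (relative && "relative" %in% names(profiles)) "relative" else "smooth"
  ggplot2::ggplot(tibble::as_tibble(profiles),
                  ggplot2::aes(x = .data$pt, y = .data[[ycol]], colour = .data$set)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "pseudotime",
                  y = if (ycol == "relative") "relative activity" else "smoothed GSZ") +
    ggplot2::theme_minimal()
}

#' Plot a biaxial signature trajectory
#'
#' @param pair A `trajectory_pair` (see [biaxial_trajectory()]) or a named
#'   list of them (one per branch).
#' @param call Optional `typology_call` used for the title.
#' @return A ggplot object; points are shaded by pseudotime.
#' @export
plot_trajectory <- function(pair, call = NULL) {
  pairs <- if (is.data.frame(pair)) list(branch = pair) else pair
  if (is.null(names(pairs))) names(pairs) <- sprintf("branch_%d", seq_along(pairs))
  d <- dplyr::bind_rows(purrr::imap(pairs, ~ dplyr::mutate(tibble::as_tibble(.x), branch = .y)))
  set_a <- attr(pairs[[1L]], "set_a") %||% "a"
  set_b <- attr(pairs[[1L]], "set_b") %||% "b"
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                       group = .data$branch, colour = .data$pt)) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::labs(x = set_a, y = set_b, colour = "pseudotime") +
    ggplot2::theme_minimal()
  if (!is.null(call)) {
    p <- p + ggplot2::ggtitle(sprintf("%s vs %s: %s", set_a, set_b, call$label[1L]))
  }
  p
}
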