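#' LOESS-smooth per-cell values along pseudotime
#'
#' Tri-cube-weighted local polynomial regression (LOESS) of the raw values
#' against pseudotime, evaluated at each observed pseudotime. The fit uses
#' exact computation (`surface = "direct"`), so results are deterministic and
#' a local-linear fit reproduces an exactly linear signal.
#'
#' @param pt Per-cell pseudotimes.
#' @param values Per-cell raw values (e.g. a GSZ vector), same length.
#' @param span LOESS span in (0, 1\]; fraction of cells in each local window
#'   (default 0.5).
#' @param degree Local polynomial degree, 1 or 2 (default 1: local-linear
#'   fits avoid the boundary overshoot of local quadratics on small,
#'   unevenly spaced pseudotime supports).
#' @param cell_ids Optional cell ids carried through to the output.
#' @param set_name Optional label carried through to the output.
#' @return A `signature_profile` tibble sorted by ascending pseudotime:
#'   columns `set`, `cell_id`, `pt`, `raw`, `smooth`; attributes `span` and
#'   `degree`.
#' @export
loess_smooth <- function(pt, values, span = 0.5, degree = 1,
                         cell_ids = NULL, set_name = "signature") {
  assert_that(is.numeric(pt) && is.numeric(values) && length(pt) == length(values),
              "`pt` and `values` must be numeric vectors of equal length")
  n <- length(pt)
  assert_that(degree %in% c(1L, 2L), "`degree` must be 1 or 2")
  assert_that(is_scalar_num(span) && span > 0 && span <= 1, "`span` must be in (0, 1]")
  assert_that(n >= max(5L, 3L * degree), "too few cells for LOESS smoothing")
  if (floor(span * n) < degree + 2L) {
    stop_ptdyn(sprintf("LOESS window holds %d point(s) but degree %d needs at least %d: increase `span`",
                       floor(span * n), degree, degree + 2L))
  }
  cell_ids <- cell_ids %||% sprintf("cell_%03d", seq_len(n))
  ord <- order(pt, cell_ids)
  df <- data.frame(pt = pt[ord], raw = values[ord])
  fit <- stats::loess(raw ~ pt, data = df, span = span, degree = degree,
                      family = "gaussian", surface = "direct")
  out <- tibble::tibble(
    set = set_name,
    cell_id = cell_ids[ord],
    pt = df$pt,
    raw = df$raw,
    smooth = unname(stats::predict(fit, newdata = df))
  )
  attr(out, "span") <- span
  attr(out, "degree") <- as.integer(degree)
  class(out) <- c("signature_profile", class(out))
  out
}

#' Smooth every signature of a GSZ table along pseudotime
#'
#' @param gsz_long Long tibble with columns `set`, `cell_id`, `gsz` (from
#'   [score_gene_sets()]).
#' @param pt_tbl Tibble with columns `cell_id`, `pt` (from a
#'   `pseudotime_result`'s `$pt`).
#' @inheritParams loess_smooth
#' @return A long `signature_profile` tibble over all sets, with a `relative`
#'   column when `rescale = TRUE` (sets whose smooth is constant are left
#'   `NA` in `relative`).
#' @param rescale Also compute [relative_activity()] per set (default TRUE).
#' @export
profile_signatures <- function(gsz_long, pt_tbl, span = 0.5, degree = 1, rescale = TRUE) {
  assert_that(all(c("set", "cell_id", "gsz") %in% names(gsz_long)),
              "`gsz_long` needs columns set, cell_id, gsz")
  assert_that(all(c("cell_id", "pt") %in% names(pt_tbl)),
              "`pt_tbl` needs columns cell_id, pt")
  joined <- dplyr::inner_join(gsz_long, pt_tbl, by = "cell_id")
  assert_that(nrow(joined) > 0L, "no shared cells between GSZ table and pseudotime")
  out <- joined %>%
    dplyr::group_by(.data$set) %>%
    dplyr::group_map(~ loess_smooth(.x$pt, .x$gsz, span = span, degree = degree,
                                    cell_ids = .x$cell_id, set_name = .y$set)) %>%
    dplyr::bind_rows()
  if (rescale) {
    out <- out %>%
      dplyr::group_by(.data$set) %>%
      dplyr::mutate(relative = if (diff(range(.data$smooth)) > 0) {
        (.data$smooth - min(.data$smooth)) / diff(range(.data$smooth))
      } else {
        NA_real_
      }) %>%
      dplyr::ungroup()
  }
  attr(out, "span") <- span
  attr(out, "degree") <- as.integer(degree)
  class(out) <- c("signature_profile", class(out))
  out
}

#' Relative activity of a smoothed profile
#'
#' Rescales the smoothed profile affinely so its minimum is exactly 0 and its
#' maximum exactly 1, making different cellular programs directly comparable.
#'
#' @param profile A `signature_profile` (from [loess_smooth()]), or a numeric
#'   vector of smoothed values.
#' @return The profile with a `relative` column (or the rescaled vector).
#' @export
relative_activity <- function(profile) {
  v <- if (is.data.frame(profile)) profile$smooth else as.numeric(profile)
  rng <- range(v)
  if (rng[2L] - rng[1L] <= 0) stop_ptdyn("degenerate profile: smooth is constant")
  rel <- (v - rng[1L]) / (rng[2L] - rng[1L])
  if (is.data.frame(profile)) {
    profile$relative <- rel
    profile
  } else {
    rel
  }
}

#' Biaxial trajectory of two signatures
#'
#' Pairs the two smoothed (or relative-activity) curves point-wise along
#' ascending pseudotime, yielding the progression trajectory of one cellular
#' program against another.
#'
#' @param profile_a,profile_b `signature_profile` tibbles over the *same*
#'   cells and pseudotimes.
#' @param use Which column to pair: `"relative"` (default, if present in
#'   both) or `"smooth"`.
#' @return A `trajectory_pair` tibble: columns `pt`, `a`, `b`, ordered by
#'   pseudotime; attributes `set_a`, `set_b`.
#' @export
biaxial_trajectory <- function(profile_a, profile_b, use = c("relative", "smooth")) {
  use <- match.arg(use)
  if (use == "relative" &&
      !("relative" %in% names(profile_a) && "relative" %in% names(profile_b))) {
    use <- "smooth"
  }
  a <- dplyr::arrange(tibble::as_tibble(profile_a), .data$pt, .data$cell_id)
  b <- dplyr::arrange(tibble::as_tibble(profile_b), .data$pt, .data$cell_id)
  assert_that(nrow(a) == nrow(b) && all(a$cell_id == b$cell_id) &&
                all(abs(a$pt - b$pt) < 1e-12),
              "profiles are not over identical cells and pseudotimes")
  out <- tibble::tibble(pt = a$pt, a = a[[use]], b = b[[use]])
  attr(out, "set_a") <- a$set[1L] %||% "a"
  attr(out, "set_b") <- b$set[1L] %||% "b"
  class(out) <- c("trajectory_pair", class(out))
  out
}

#' Write signature profiles as long-format TSV
#'
#' @param profiles A `signature_profile` tibble (long, possibly several sets).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_tsv(tibble::as_tibble(profiles), path, progress = FALSE)
  invisible(path)
}
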