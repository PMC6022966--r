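#' Pairwise cell-cell distances on full expression profiles
#'
#' `correlation` is `1 - Pearson r` between cell columns (robust to per-cell
#' scale); `euclidean` is the ordinary L2 distance. Zero distances between
#' duplicated profiles are lifted to a tiny positive floor so that graph edge
#' weights stay strictly positive.
#'
#' @keywords internal
cell_distances <- function(mat, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  d <- switch(metric,
    correlation = {
      sds <- apply(mat, 2L, stats::sd)
      assert_that(all(sds > 0),
                  "correlation distance undefined: some cells have constant profiles (use metric = 'euclidean')")
      1 - stats::cor(mat)
    },
    euclidean = as.matrix(stats::dist(t(mat)))
  )
  diag(d) <- 0
  d[d < 0] <- 0  # guard tiny negative from 1 - cor rounding
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    floor_val <- if (any(off > 0)) min(off[off > 0]) * 1e-6 else 1e-12
    d[d == 0] <- floor_val
    diag(d) <- 0
  }
  d
}

#' Build an ensemble of subsampled k-nearest-neighbour graphs
#'
#' For every cell, its `k` nearest neighbours (by the chosen metric on the
#' full expression profiles) are computed once; each ensemble member then
#' keeps an independent uniform subsample of `l` of those `k` neighbours per
#' cell and symmetrizes (an edge exists if either endpoint selected it), with
#' edge weight equal to the distance. If a member graph is disconnected it is
#' repaired by repeatedly adding the globally shortest edge between two
#' components until connected. The whole construction is deterministic given
#' `seed`.
#'
#' @param mat Named numeric matrix, genes x cells (typically standardized,
#'   see [log_standardize()]).
#' @param k Neighbourhood size (default 16); must be < number of cells.
#' @param l Neighbours retained per cell in each member graph, `l <= k`
#'   (default 8). `l = k` gives a degenerate ensemble of identical graphs.
#' @param n_graphs Ensemble size (default 20).
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param seed Integer seed for the neighbour subsampling.
#' @return A `knn_ensemble`: list with `graphs` (list of igraph objects),
#'   `dist` (full distance matrix), `cell_ids` and the parameters.
#' @export
build_knn_ensemble <- function(mat, k = 16, l = 8, n_graphs = 20,
                               metric = c("correlation", "euclidean"), seed = 1L) {
  validate_expression_matrix(mat)
  metric <- match.arg(metric)
  n <- ncol(mat)
  assert_that(n >= 3L, "at least 3 cells are required")
  assert_that(is_count(k) && k < n, sprintf("`k` must be a positive integer < n_cells (%d)", n))
  assert_that(is_count(l) && l <= k, "`l` must be a positive integer <= k")
  assert_that(is_count(n_graphs), "`n_graphs` must be a positive integer")
  assert_that(is_count(seed, min = -Inf), "`seed` must be an integer")

  d <- cell_distances(mat, metric)
  cell_ids <- colnames(mat)
  # k nearest neighbours per cell, self excluded, ties broken by cell index
  nn <- t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    setdiff(ord, i)[seq_len(k)]
  }, integer(k)))

  graphs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_graphs), function(g) {
      sel <- lapply(seq_len(n), function(i) {
        if (l == k) nn[i, ] else sort(sample(nn[i, ], l))
      })
      from <- rep(seq_len(n), each = l)
      to <- unlist(sel, use.names = FALSE)
      # symmetrized union, deduplicated
      a <- pmin(from, to); b <- pmax(from, to)
      keep <- !duplicated(cbind(a, b))
      edges <- data.frame(from = cell_ids[a[keep]], to = cell_ids[b[keep]],
                          weight = d[cbind(a[keep], b[keep])])
      gr <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = cell_ids)
      bridge_components(gr, d)
    })
  })

  structure(
    list(graphs = graphs, dist = d, cell_ids = cell_ids,
         k = as.integer(k), l = as.integer(l), n_graphs = as.integer(n_graphs),
         metric = metric, seed = as.integer(seed)),
    class = "knn_ensemble"
  )
}

# Deterministically connect a graph: while more than one component remains,
# add the globally shortest edge joining two different components.
bridge_components <- function(gr, d) {
  repeat {
    comp <- igraph::components(gr)
    if (comp$no == 1L) return(gr)
    best <- NULL; best_d <- Inf
    membership <- comp$membership
    for (ci in seq_len(comp$no - 1L)) {
      ii <- which(membership == ci)
      jj <- which(membership > ci)
      sub <- d[ii, jj, drop = FALSE]
      w <- which.min(sub)
      if (sub[w] < best_d) {
        best_d <- sub[w]
        best <- c(ii[(w - 1L) %% length(ii) + 1L], jj[(w - 1L) %/% length(ii) + 1L])
      }
    }
    gr <- igraph::add_edges(gr, igraph::V(gr)$name[best], weight = best_d)
  }
}

#' @export
print.knn_ensemble <- function(x, ...) {
  cat(sprintf("<knn_ensemble> %d graphs over %d cells (k = %d, l = %d, metric = %s, seed = %d)\n",
              x$n_graphs, length(x$cell_ids), x$k, x$l, x$metric, x$seed))
  invisible(x)
}

#' Pseudotime from an ensemble of k-NN graphs
#'
#' In every member graph the trajectory of a cell is its weighted
#' shortest-path distance from the start cell; the per-cell mean over graphs,
#' affinely rescaled to \[0, 1\], is the pseudotime. The start cell gets
#' pseudotime 0.
#'
#' @param ensemble A [build_knn_ensemble()] result.
#' @param start_cell Cell id anchoring pseudotime 0 (see
#'   [select_start_cell()]).
#' @return A `pseudotime_result`: list with `pt` (tibble `cell_id`, `pt`),
#'   `start_cell`, `oriented` flag, `per_graph` (n_graphs x n_cells raw
#'   distance matrix) and `params`.
#' @export
compute_pseudotime <- function(ensemble, start_cell) {
  assert_that(inherits(ensemble, "knn_ensemble"), "`ensemble` must be a knn_ensemble")
  assert_that(start_cell %in% ensemble$cell_ids,
              sprintf("start cell '%s' is not a vertex", start_cell))
  per_graph <- t(vapply(ensemble$graphs, function(gr) {
    as.numeric(igraph::distances(gr, v = start_cell, weights = igraph::E(gr)$weight))
  }, numeric(length(ensemble$cell_ids))))
  colnames(per_graph) <- ensemble$cell_ids
  if (!all(is.finite(per_graph))) {
    stop_ptdyn("internal error: unreachable cell despite bridged graphs")
  }
  mean_d <- colMeans(per_graph)
  rng <- range(mean_d)
  assert_that(rng[2L] > rng[1L], "all cells are equidistant from the start cell")
  pt <- (mean_d - rng[1L]) / (rng[2L] - rng[1L])
  structure(
    list(
      pt = tibble::tibble(cell_id = ensemble$cell_ids, pt = unname(pt)),
      start_cell = start_cell,
      oriented = FALSE,
      per_graph = per_graph,
      params = ensemble[c("k", "l", "n_graphs", "metric", "seed")]
    ),
    class = "pseudotime_result"
  )
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat(sprintf("<pseudotime_result> %d cells, start '%s'%s (k = %d, l = %d, %d graphs, %s)\n",
              nrow(x$pt), x$start_cell, if (x$oriented) ", oriented" else "",
              x$params$k, x$params$l, x$params$n_graphs, x$params$metric))
  invisible(x)
}

#' Select the pseudotime start cell from a stromal signature
#'
#' The cell with the highest stromal GSZ anchors pseudotime 0 (cells with a
#' high stromal signature mark the earliest progression stage). Ties break to
#' the lexicographically smallest cell id.
#'
#' @param standardized Gene-level score matrix ([log_standardize()]).
#' @param stromal_genes Character vector; must intersect the matrix genes.
#' @param lambda Passed to [gsz_score()].
#' @return A cell id.
#' @export
select_start_cell <- function(standardized, stromal_genes, lambda = 0) {
  if (ncol(standardized) == 1L) return(colnames(standardized))
  g <- gsz_score(standardized, stromal_genes, lambda = lambda)
  ord <- order(-g$gsz, g$cell_id)
  g$cell_id[ord[1L]]
}

#' Orient pseudotime by proliferative activity
#'
#' Highly proliferative cells belong at high pseudotime. If the mean
#' proliferative GSZ of the top pseudotime decile is below that of the bottom
#' decile, pseudotime is reversed (`pt -> 1 - pt`). Applying the function
#' twice never flips back and forth: it is idempotent on an already oriented
#' result.
#'
#' @param result A [compute_pseudotime()] result.
#' @param proliferative_gsz Per-cell proliferative scores: either a tibble
#'   with columns `cell_id` and `gsz` (as from [gsz_score()]) or a numeric
#'   vector named by cell id.
#' @return The (possibly reversed) `pseudotime_result` with `oriented = TRUE`.
#' @export
orient_pseudotime <- function(result, proliferative_gsz) {
  assert_that(inherits(result, "pseudotime_result"), "`result` must be a pseudotime_result")
  g <- if (is.data.frame(proliferative_gsz)) {
    stats::setNames(proliferative_gsz$gsz, proliferative_gsz$cell_id)
  } else {
    proliferative_gsz
  }
  assert_that(all(result$pt$cell_id %in% names(g)),
              "proliferative GSZ missing for some cells")
  g <- g[result$pt$cell_id]
  n <- nrow(result$pt)
  n_dec <- max(1L, floor(n / 10))
  ord <- order(result$pt$pt)
  bottom <- ord[seq_len(n_dec)]
  top <- ord[seq.int(n - n_dec + 1L, n)]
  if (mean(g[top]) < mean(g[bottom])) {
    result$pt$pt <- 1 - result$pt$pt
  }
  result$oriented <- TRUE
  result
}

#' One-call pseudotime inference
#'
#' Standardizes the matrix, anchors the start cell on the stromal signature,
#' builds the graph ensemble, averages shortest-path distances and orients by
#' the proliferative signature.
#'
#' @inheritParams build_knn_ensemble
#' @param stromal_genes,proliferative_genes Anchor gene sets; orientation is
#'   skipped when `proliferative_genes` is `NULL`.
#' @param standardized Optional pre-standardized matrix (otherwise computed
#'   from `mat` with [log_standardize()]).
#' @return A `pseudotime_result`.
#' @export
infer_pseudotime <- function(mat, stromal_genes, proliferative_genes = NULL,
                             k = 16, l = 8, n_graphs = 20,
                             metric = c("correlation", "euclidean"), seed = 1L,
                             standardized = NULL) {
  metric <- match.arg(metric)
  std <- standardized %||% log_standardize(mat)
  start <- select_start_cell(std, stromal_genes)
  ens <- build_knn_ensemble(std, k = k, l = l, n_graphs = n_graphs,
                            metric = metric, seed = seed)
  res <- compute_pseudotime(ens, start)
  if (!is.null(proliferative_genes)) {
    res <- orient_pseudotime(res, gsz_score(std, proliferative_genes))
  }
  res
}

#' Detect an initial slow pseudotime component
#'
#' Fits pseudotime (y) against normalized cell rank (x) with a single line
#' and with a continuous two-segment line whose breakpoint is scanned over
#' the interior ranks. When the two-segment fit reduces the residual sum of
#' squares by at least `threshold` (relative), the fitted pseudotime at the
#' breakpoint is reported as `pt_star` — the characteristic pseudotime where
#' the flat initial component hands over to the fast one.
#'
#' @param result A `pseudotime_result`, or a numeric vector of pseudotimes.
#' @param threshold Minimal relative RSS reduction for a breakpoint call
#'   (default 0.25).
#' @param margin Smallest number of cells on each side of a candidate
#'   breakpoint (default 5).
#' @return A one-row tibble (class `breakpoint_result`): `pt_star` (NA when no
#'   breakpoint is called), `slope_early`, `slope_late`, `improvement`,
#'   `break_rank` (normalized rank of the best candidate breakpoint).
#' @export
detect_slow_component <- function(result, threshold = 0.25, margin = 5L) {
  pt <- if (inherits(result, "pseudotime_result")) result$pt$pt else as.numeric(result)
  n <- length(pt)
  assert_that(n >= 20L, "breakpoint detection needs at least 20 cells")
  y <- sort(pt)
  x <- (seq_len(n) - 1) / (n - 1)
  rss1 <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)

  candidates <- seq.int(margin + 1L, n - margin)
  best <- list(rss = Inf, xb = NA_real_, fit = NULL)
  for (i in candidates) {
    xb <- x[i]
    X <- cbind(1, x, pmax(x - xb, 0))
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    if (rss < best$rss) best <- list(rss = rss, xb = xb, fit = f)
  }
  # an (all but) exact single-line fit leaves nothing to improve on
  tss <- sum((y - mean(y))^2)
  improvement <- if (rss1 > 1e-10 * max(tss, 1)) {
    max(0, (rss1 - best$rss) / rss1)
  } else {
    0
  }
  co <- best$fit$coefficients
  slope_early <- unname(co[2L])
  slope_late <- unname(co[2L] + co[3L])
  pt_star <- if (improvement >= threshold) {
    unname(co[1L] + co[2L] * best$xb)
  } else {
    NA_real_
  }
  structure(
    tibble::tibble(pt_star = pt_star, slope_early = slope_early,
                   slope_late = slope_late, improvement = improvement,
                   break_rank = best$xb),
    class = c("breakpoint_result", "tbl_df", "tbl", "data.frame")
  )
}

#' Write a pseudotime result and its provenance
#'
#' @param result A `pseudotime_result`.
#' @param dir Output directory: writes `pt.tsv` (cell_id, pt) and
#'   `pt_params.json`.
#' @return `dir`, invisibly.
#' @export
write_pseudotime <- function(result, dir) {
  assert_that(inherits(result, "pseudotime_result"), "`result` must be a pseudotime_result")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(result$pt, file.path(dir, "pt.tsv"), progress = FALSE)
  prov <- c(result$params, list(start_cell = result$start_cell, oriented = result$oriented))
  jsonlite::write_json(prov, file.path(dir, "pt_params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
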