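# Five cells on a noise-free 1-D expression gradient: the k-NN structure and
# shortest-path pseudotime are exactly predictable.
gradient_matrix <- function(n = 5, n_genes = 10, spacing = 1) {
  vals <- outer(rep(1, n_genes), seq_len(n) * spacing)
  vals <- vals + (seq_len(n_genes) - mean(seq_len(n_genes))) # distinct rows
  toy_matrix(vals, n_genes, n)
}

test_that("a 1-D gradient with k = 2 yields the consecutive-cell path graph", {
  m <- gradient_matrix()
  ens <- build_knn_ensemble(m, k = 2, l = 2, n_graphs = 1, metric = "euclidean", seed = 1)
  got <- igraph::as_edgelist(ens$graphs[[1]])
  got <- apply(got, 1, function(e) paste(sort(e), collapse = "-"))
  # brute force: for each cell the 2 nearest by pairwise distance
  d <- as.matrix(dist(t(m)))
  want <- unique(unlist(lapply(seq_len(5), function(i) {
    nn <- order(d[i, ])[2:3]
    paste(vapply(nn, function(j) paste(sort(colnames(m)[c(i, j)]), collapse = "-"),
                 character(1)), "")
  })))
  want <- trimws(want)
  expect_setequal(got, c("c01-c02", "c02-c03", "c03-c04", "c04-c05", "c01-c03", "c03-c05"))
  expect_true(all(c("c01-c02", "c02-c03", "c03-c04", "c04-c05") %in% want))
})

test_that("pseudotime on a unit path graph is the rescaled hop distance", {
  # equally spaced gradient: shortest-path distance from the first cell is
  # proportional to position, so pt = 0, .25, .5, .75, 1
  m <- gradient_matrix()
  ens <- build_knn_ensemble(m, k = 2, l = 2, n_graphs = 3, metric = "euclidean", seed = 1)
  res <- compute_pseudotime(ens, "c01")
  expect_equal(res$pt$pt, c(0, 0.25, 0.5, 0.75, 1))
  expect_identical(res$start_cell, "c01")
  expect_false(res$oriented)
})

test_that("l = k gives a degenerate ensemble of identical graphs", {
  m <- quiet_std(monotone_dataset(30, noise_sd = 0.3, seed = 2)$matrix)
  ens <- build_knn_ensemble(m, k = 5, l = 5, n_graphs = 4, metric = "euclidean", seed = 1)
  e1 <- igraph::as_edgelist(ens$graphs[[1]])
  for (g in ens$graphs[-1]) expect_identical(igraph::as_edgelist(g), e1)
})

test_that("ensemble parameters are validated", {
  m <- gradient_matrix()
  expect_error(build_knn_ensemble(m, k = 5, l = 2, seed = 1), "k")
  expect_error(build_knn_ensemble(m, k = 2, l = 3, seed = 1), "l")
  expect_error(build_knn_ensemble(m[, 1:2], k = 1, l = 1, seed = 1), "3 cells")
})

test_that("every ensemble member is connected after bridging", {
  for (s in 1:100) {
    ds <- simulate_expression(
      30, modules = list(module_spec("up", "linear_up", 10, amplitude = 3)),
      n_background = 10, noise_sd = 1, dropout_rate = 0.3, seed = s)
    std <- quiet_std(ds$matrix)
    ens <- build_knn_ensemble(std, k = 4, l = 1, n_graphs = 2, seed = s)
    for (g in ens$graphs) {
      expect_equal(igraph::components(g)$no, 1)
      expect_true(all(igraph::E(g)$weight > 0))
    }
  }
})

test_that("noise-free pseudotime recovers the latent ordering exactly", {
  ds <- monotone_dataset(84)
  std <- quiet_std(ds$matrix)
  start <- ds$true_pt$cell_id[which.min(ds$true_pt$true_pt)]
  ens <- build_knn_ensemble(std, k = 16, l = 16, n_graphs = 1, metric = "euclidean", seed = 1)
  res <- compute_pseudotime(ens, start)
  expect_equal(cor(res$pt$pt, ds$true_pt$true_pt, method = "spearman"), 1)
  expect_equal(range(res$pt$pt), c(0, 1))
  expect_equal(res$pt$pt[res$pt$cell_id == start], 0)
})

test_that("the start cell is the stromal-high cell, with deterministic ties", {
  # a strictly monotone stromal program pins the start sharply
  ds <- monotone_dataset(100, noise_sd = 0.5, dropout_rate = 0.2, seed = 6)
  std <- quiet_std(preprocess_matrix(ds$matrix))
  start <- select_start_cell(std, ds$gmt$stromal)
  tp <- ds$true_pt$true_pt[match(start, ds$true_pt$cell_id)]
  expect_lte(mean(ds$true_pt$true_pt < tp), 0.1)  # lowest true-pt decile
  # a one-cell matrix returns its only cell
  one <- toy_matrix(1:3, 3, 1, genes = c("a", "b", "c"), cells = "only")
  expect_identical(select_start_cell(one, c("a", "b")), "only")
  # two cells with identical profiles tie-break lexicographically
  trio <- toy_matrix(c(5, 5, 0, 5, 5, 0, 1, 1, 3), 3, 3,
                     genes = c("a", "b", "c"), cells = c("zcell", "acell", "mid"))
  expect_identical(select_start_cell(quiet_std(trio), c("a", "b")), "acell")
})

test_that("orientation flips exactly when proliferative activity decreases with pt", {
  ds <- simulate_expression(60, modules = default_modules(), noise_sd = 0.5,
                            dropout_rate = 0.1, seed = 7)
  std <- quiet_std(preprocess_matrix(ds$matrix))
  res <- infer_pseudotime(ds$matrix, ds$gmt$stromal, seed = 7, standardized = std)
  prolif <- gsz_score(std, ds$gmt$cellcycle)
  oriented <- orient_pseudotime(res, prolif)
  # idempotence on an already oriented result
  again <- orient_pseudotime(oriented, prolif)
  expect_equal(again$pt, oriented$pt)
  # involution: flipping the input is undone
  flipped <- oriented
  flipped$pt$pt <- 1 - flipped$pt$pt
  expect_equal(orient_pseudotime(flipped, prolif)$pt, oriented$pt)
  # ground truth: top decile has higher proliferative score than bottom
  g <- setNames(prolif$gsz, prolif$cell_id)[oriented$pt$cell_id]
  ord <- order(oriented$pt$pt)
  expect_gt(mean(g[tail(ord, 6)]), mean(g[head(ord, 6)]))
})

test_that("ensemble pseudotime is stable across subsampling seeds and k", {
  ds <- simulate_expression(84, modules = default_modules(), noise_sd = 0,
                            dropout_rate = 0, seed = 5)
  std <- quiet_std(ds$matrix)
  r1 <- infer_pseudotime(ds$matrix, ds$gmt$stromal, ds$gmt$cellcycle,
                         seed = 11, standardized = std)
  r2 <- infer_pseudotime(ds$matrix, ds$gmt$stromal, ds$gmt$cellcycle,
                         seed = 99, standardized = std)
  expect_gte(cor(r1$pt$pt, r2$pt$pt, method = "spearman"), 0.98)
  pts <- lapply(c(10, 16, 20), function(k)
    infer_pseudotime(ds$matrix, ds$gmt$stromal, ds$gmt$cellcycle, k = k,
                     seed = 11, standardized = std)$pt$pt)
  expect_gte(cor(pts[[1]], pts[[2]], method = "spearman"), 0.95)
  expect_gte(cor(pts[[2]], pts[[3]], method = "spearman"), 0.95)
  expect_gte(cor(pts[[1]], pts[[3]], method = "spearman"), 0.95)
  # under moderate noise the orderings remain close
  dsn <- simulate_expression(84, modules = default_modules(), noise_sd = 0.5,
                             dropout_rate = 0.1, seed = 5)
  stdn <- quiet_std(preprocess_matrix(dsn$matrix))
  ptn <- lapply(c(10, 20), function(k)
    infer_pseudotime(dsn$matrix, dsn$gmt$stromal, dsn$gmt$cellcycle, k = k,
                     seed = 11, standardized = stdn)$pt$pt)
  expect_gte(cor(ptn[[1]], ptn[[2]], method = "spearman"), 0.9)
})

test_that("a linear pt-vs-rank curve yields no breakpoint", {
  res <- detect_slow_component(seq(0, 1, length.out = 50))
  expect_true(is.na(res$pt_star))
  expect_lt(res$improvement, 0.25)
})

test_that("a constructed two-segment curve recovers its breakpoint pseudotime", {
  # slow slope up to 91% of the ranks, then fast: break sits at pt = 0.25
  n <- 100
  x <- (seq_len(n) - 1) / (n - 1)
  xb <- 0.909
  y <- ifelse(x <= xb, 0.1 * x, 0.1 * xb + 3 * (x - xb))
  y <- y / max(y)
  res <- detect_slow_component(y)
  expect_false(is.na(res$pt_star))
  expect_lt(abs(res$pt_star - 0.25), 0.05)
  expect_gt(res$slope_late, res$slope_early)
  expect_gte(res$improvement, 0.25)
})

test_that("breakpoint detection needs at least 20 cells", {
  expect_error(detect_slow_component(runif(19)), "20 cells")
})

test_that("tidy and glance summarize a pseudotime result", {
  ds <- monotone_dataset(30, noise_sd = 0.2, seed = 3)
  std <- quiet_std(ds$matrix)
  res <- infer_pseudotime(ds$matrix, ds$gmt$stromal, seed = 3,
                          standardized = std, metric = "euclidean")
  td <- tidy(res)
  expect_identical(names(td), c("cell_id", "pt", "rank"))
  expect_identical(td$rank, 1:30)
  gl <- glance(res)
  expect_identical(gl$n_cells, 30L)
  expect_identical(gl$metric, "euclidean")
  expect_false(gl$oriented)
})
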