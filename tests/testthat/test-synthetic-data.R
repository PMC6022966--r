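test_that("generation is deterministic in the seed and sensitive to it", {
  a <- simulate_expression(20, seed = 42)
  b <- simulate_expression(20, seed = 42)
  c <- simulate_expression(20, seed = 43)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$true_pt, b$true_pt)
  expect_false(identical(a$matrix, c$matrix))
})

test_that("every temporal shape maps [0,1] into [0,1] with finite endpoints", {
  t <- seq(0, 1, length.out = 201)
  for (shape in module_shapes()) {
    f <- shape_value(shape, t, onset = 0.4, steepness = 7)
    expect_true(all(is.finite(f)), info = shape)
    expect_true(all(f >= 0 & f <= 1), info = shape)
  }
  # documented closed forms at a spot value
  expect_equal(shape_value("decreasing_sigmoid", 0.3, onset = 0.3, steepness = 10), 0.5)
  expect_equal(shape_value("delayed_ramp", c(0.2, 0.65), onset = 0.3), c(0, 0.5))
  expect_equal(shape_value("saturating", 0.5, steepness = 2), 1 - exp(-1))
  expect_equal(shape_value("bipolar_high", 0.5, onset = 0.5) +
                 shape_value("bipolar_low", 0.5, onset = 0.5), 1)
})

test_that("noise-free monotone module expression is strictly monotone in true pseudotime", {
  ds <- simulate_expression(
    30, modules = list(module_spec("up", "linear_up", 5, amplitude = 2)),
    n_background = 3, noise_sd = 0, dropout_rate = 0, seed = 1)
  ord <- order(ds$true_pt$true_pt)
  for (g in ds$gmt$up) {
    expect_true(all(diff(ds$matrix[g, ord]) > 0), info = g)
  }
  # ranking by module mean equals ranking by true pseudotime
  module_mean <- colMeans(ds$matrix[ds$gmt$up, ])
  expect_identical(order(module_mean), ord)
})

test_that("failed-cell marking zeroes both housekeeping genes in the exact fraction", {
  ds <- simulate_expression(100, frac_failed_cells = 0.1, seed = 9)
  failed <- colSums(ds$matrix[c("ACTB", "GAPDH"), ] > 0) == 0
  expect_identical(sum(failed), 10L)
  expect_setequal(colnames(ds$matrix)[failed], ds$params$failed_cells)
  # all other cells express both housekeeping genes
  expect_true(all(ds$matrix[c("ACTB", "GAPDH"), !failed] > 0))
})

test_that("empirical dropout rate converges to the nominal rate", {
  # ~1.2e5 non-housekeeping entries; baseline far from zero so that every
  # observed zero comes from dropout
  ds <- simulate_expression(
    400, modules = list(module_spec("up", "linear_up", 200, amplitude = 1)),
    n_background = 100, noise_sd = 0.1, dropout_rate = 0.2, seed = 7, baseline = 5)
  entries <- ds$matrix[setdiff(rownames(ds$matrix), c("ACTB", "GAPDH")), ]
  p_hat <- mean(entries == 0)
  se <- sqrt(0.2 * 0.8 / length(entries))
  expect_lt(abs(p_hat - 0.2), 3 * se)
})

test_that("bipolar module means are anti-correlated across cells", {
  ds <- simulate_expression(
    50, modules = list(module_spec("hi", "bipolar_high", 10),
                       module_spec("lo", "bipolar_low", 10)),
    n_background = 0, noise_sd = 0, dropout_rate = 0, seed = 3)
  hi <- colMeans(ds$matrix[ds$gmt$hi, ])
  lo <- colMeans(ds$matrix[ds$gmt$lo, ])
  expect_lt(cor(hi, lo), 0)
})

test_that("degenerate generator inputs are rejected", {
  expect_error(simulate_expression(5), "meaningless")
  expect_error(simulate_expression(20, noise_sd = -1), "noise_sd")
  expect_error(simulate_expression(20, dropout_rate = 1), "dropout_rate")
  expect_error(simulate_expression(20, modules = list()), "non-empty")
})

test_that("dataset round-trips through TSV, MatrixMarket and GMT files", {
  ds <- simulate_expression(15, modules = list(module_spec("up", "linear_up", 4)),
                            n_background = 2, seed = 2)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  tsv <- read_expression_tsv(file.path(dir, "matrix.tsv"))
  expect_equal(tsv, ds$matrix)
  mtx <- read_expression_mtx(file.path(dir, "mtx", "matrix.mtx"),
                             file.path(dir, "mtx", "genes.tsv"),
                             file.path(dir, "mtx", "barcodes.tsv"))
  expect_equal(mtx, ds$matrix, tolerance = 1e-5)  # MatrixMarket text precision
  gmt <- read_gmt(file.path(dir, "modules.gmt"))
  expect_identical(gmt$up, ds$gmt$up)
  pt <- readr::read_tsv(file.path(dir, "true_pt.tsv"), show_col_types = FALSE)
  expect_equal(pt$true_pt, ds$true_pt$true_pt)
})
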