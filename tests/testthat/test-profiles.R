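test_that("local-linear LOESS reproduces an exactly linear signal", {
  pt <- seq(0, 1, length.out = 40)
  v <- 2 + 3 * pt
  prof <- loess_smooth(pt, v, span = 0.5, degree = 1)
  expect_lt(max(abs(prof$smooth - prof$raw)), 1e-8)
  # constant input stays constant
  prof0 <- loess_smooth(pt, rep(4, 40), span = 0.5, degree = 2)
  expect_equal(prof0$smooth, rep(4, 40))
})

test_that("smoothing a noisy sine reduces the error to the true curve", {
  withr::with_seed(1, {
    pt <- sort(runif(200))
    truth <- sin(2 * pi * pt)
    v <- truth + rnorm(200, sd = 0.4)
    prof <- loess_smooth(pt, v, span = 0.3, degree = 2, cell_ids = sprintf("c%03d", 1:200))
    truth_sorted <- sin(2 * pi * prof$pt)
    rmse_raw <- sqrt(mean((prof$raw - truth_sorted)^2))
    rmse_smooth <- sqrt(mean((prof$smooth - truth_sorted)^2))
    expect_lt(rmse_smooth, rmse_raw)
  })
})

test_that("too-small smoothing windows are rejected with advice", {
  expect_error(loess_smooth(runif(20), runif(20), span = 0.1, degree = 2), "span")
  expect_error(loess_smooth(runif(4), runif(4)), "few cells")
})

test_that("relative activity is an exact affine map onto [0, 1]", {
  expect_equal(relative_activity(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.2, 1)
  expect_equal(relative_activity(v), v)  # idempotent on [0, 1] with extremes
  withr::with_seed(2, {
    r <- relative_activity(rnorm(50))
    expect_equal(min(r), 0)
    expect_equal(max(r), 1)
  })
  expect_error(relative_activity(rep(1, 10)), "degenerate")
})

test_that("smooth-then-rescale is invariant to affine transforms of the raw values", {
  withr::with_seed(3, {
    pt <- sort(runif(60))
    v <- cumsum(rnorm(60))
  })
  a <- relative_activity(loess_smooth(pt, v)$smooth)
  b <- relative_activity(loess_smooth(pt, 5 * v - 7)$smooth)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("biaxial trajectories pair the two smooths along pseudotime", {
  pt <- seq(0, 1, length.out = 30)
  ids <- sprintf("c%02d", 1:30)
  pa <- loess_smooth(pt, pt, degree = 1, cell_ids = ids, set_name = "up")
  pb <- loess_smooth(pt, 1 - pt, degree = 1, cell_ids = ids, set_name = "down")
  pair <- biaxial_trajectory(pa, pb, use = "smooth")
  expect_equal(pair$b, 1 - pair$a, tolerance = 1e-8)
  expect_false(is.unsorted(pair$pt))
  expect_identical(attr(pair, "set_a"), "up")
  # a = b lies on the diagonal
  diag_pair <- biaxial_trajectory(pa, pa, use = "smooth")
  expect_equal(diag_pair$a, diag_pair$b)
  # swapping inputs transposes the curve
  swapped <- biaxial_trajectory(pb, pa, use = "smooth")
  expect_equal(swapped$a, pair$b)
  expect_equal(swapped$b, pair$a)
})

test_that("biaxial pairing demands identical cells and pseudotimes", {
  pt <- seq(0, 1, length.out = 30)
  ids <- sprintf("c%02d", 1:30)
  pa <- loess_smooth(pt, pt, cell_ids = ids)
  pb <- loess_smooth(pt[-1], pt[-1], cell_ids = ids[-1])
  expect_error(biaxial_trajectory(pa, pb), "identical cells")
})

test_that("profile_signatures smooths every set over shared cells", {
  ds <- simulate_expression(40, modules = default_modules(), noise_sd = 0.5,
                            dropout_rate = 0.1, seed = 4)
  std <- quiet_std(preprocess_matrix(ds$matrix))
  gsz <- suppressWarnings(score_gene_sets(std, ds$gmt))
  pt_tbl <- tibble::tibble(cell_id = colnames(std),
                           pt = rank(-gsz$gsz[gsz$set == "stromal"]) / ncol(std))
  prof <- profile_signatures(gsz, pt_tbl)
  expect_setequal(unique(prof$set), names(ds$gmt))
  expect_identical(nrow(prof), nrow(gsz))
  per_set <- dplyr::summarise(dplyr::group_by(prof, set),
                              lo = min(relative), hi = max(relative))
  expect_equal(per_set$lo, rep(0, nrow(per_set)))
  expect_equal(per_set$hi, rep(1, nrow(per_set)))
})
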