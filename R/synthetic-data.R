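#' Temporal shape library for synthetic gene modules
#'
#' Every shape maps a latent pseudotime t in \[0, 1\] to an activation level in
#' \[0, 1\]:
#'
#' * `decreasing_sigmoid`: `1 / (1 + exp(steepness * (t - onset)))` — early
#'   programs that shut down (stromal).
#' * `delayed_ramp`: 0 until `onset`, then linear to 1 — delayed but steady
#'   activation (cell cycle).
#' * `saturating`: `1 - exp(-steepness * t)` — fast rise to a plateau
#'   (oxidative phosphorylation).
#' * `late_rise`: a delayed ramp intended for large `onset` — late activation
#'   (aerobic glycolysis).
#' * `bipolar_high` / `bipolar_low`: a rising logistic and its complement —
#'   the two poles of an antagonistic program pair (MITF / AXL).
#' * `linear_up` / `linear_down`: `t` and `1 - t` — monotone references
#'   (active / poised promoter activity).
#' * `constant`: 1 everywhere.
#'
#' @param shape One of the shape names above.
#' @param t Numeric vector of latent pseudotimes in \[0, 1\].
#' @param onset Pseudotime location of half-activation (or ramp start).
#' @param steepness Positive slope parameter of the sigmoid/exponential shapes.
#' @return Numeric vector of activations in \[0, 1\].
#' @export
shape_value <- function(shape, t, onset = 0.5, steepness = 10) {
  assert_that(is_scalar_num(onset) && onset >= 0 && onset <= 1,
              "`onset` must be in [0, 1]")
  assert_that(is_scalar_num(steepness) && steepness > 0, "`steepness` must be > 0")
  shape <- match.arg(shape, module_shapes())
  ramp <- function(t, onset) ifelse(t < onset, 0, (t - onset) / (1 - onset))
  switch(shape,
    decreasing_sigmoid = 1 / (1 + exp(steepness * (t - onset))),
    delayed_ramp = ramp(t, onset),
    saturating = 1 - exp(-steepness * t),
    late_rise = ramp(t, onset),
    bipolar_high = 1 / (1 + exp(-steepness * (t - onset))),
    bipolar_low = 1 - 1 / (1 + exp(-steepness * (t - onset))),
    linear_up = t,
    linear_down = 1 - t,
    constant = rep(1, length(t))
  )
}

#' @rdname shape_value
#' @export
module_shapes <- function() {
  c("decreasing_sigmoid", "delayed_ramp", "saturating", "late_rise",
    "bipolar_high", "bipolar_low", "linear_up", "linear_down", "constant")
}

#' Specify one synthetic gene module
#'
#' A module is a block of genes whose mean log2 activity follows a shared
#' temporal shape along the latent pseudotime.
#'
#' @param name Module label; also the prefix of its gene ids and the name of
#'   the derived gene set.
#' @param shape One of [module_shapes()].
#' @param n_genes Number of genes in the module (>= 1).
#' @param amplitude Dynamic range in log2-expression units (>= 0).
#' @param onset,steepness Shape parameters, see [shape_value()].
#' @return A `module_spec` list.
#' @export
module_spec <- function(name, shape, n_genes, amplitude = 3, onset = 0.5, steepness = 10) {
  assert_that(is.character(name) && length(name) == 1L && nzchar(name),
              "`name` must be a non-empty string")
  shape <- match.arg(shape, module_shapes())
  assert_that(is_count(n_genes), "`n_genes` must be a positive integer")
  assert_that(is_scalar_num(amplitude) && amplitude >= 0, "`amplitude` must be >= 0")
  structure(
    list(name = name, shape = shape, n_genes = as.integer(n_genes),
         amplitude = amplitude, onset = onset, steepness = steepness),
    class = "module_spec"
  )
}

#' @export
print.module_spec <- function(x, ...) {
  cat(sprintf("<module_spec> %s: %d genes, shape %s (amplitude %.2g, onset %.2g, steepness %.2g)\n",
              x$name, x$n_genes, x$shape, x$amplitude, x$onset, x$steepness))
  invisible(x)
}

#' Default module set emulating the melanoma progression programs
#'
#' Eight modules mirroring the qualitative temporal patterns of the programs
#' tracked by the pipeline: a decaying stromal program, a delayed cell-cycle
#' ramp, fast-saturating oxphos, late-rising glycolysis, an antagonistic
#' MITF/AXL logistic pair, and anti-correlated linear active/poised promoter
#' activities (TssA up, TssP down).
#'
#' @param axl_high If `TRUE`, swap the MITF/AXL polarity so that AXL ends high
#'   (the NRAS-mutant-like state); default `FALSE` (MITF ends high).
#' @return List of [module_spec()] objects.
#' @export
default_modules <- function(axl_high = FALSE) {
  list(
    module_spec("stromal",    "decreasing_sigmoid", 40, amplitude = 3, onset = 0.35, steepness = 10),
    module_spec("cellcycle",  "delayed_ramp",       40, amplitude = 3, onset = 0.30),
    module_spec("oxphos",     "saturating",         30, amplitude = 3, steepness = 5),
    module_spec("glycolysis", "late_rise",          25, amplitude = 3, onset = 0.60),
    module_spec("MITF", if (axl_high) "bipolar_low" else "bipolar_high",
                25, amplitude = 3, onset = 0.5, steepness = 8),
    module_spec("AXL",  if (axl_high) "bipolar_high" else "bipolar_low",
                25, amplitude = 3, onset = 0.5, steepness = 8),
    module_spec("TssA", "linear_up",   30, amplitude = 2),
    module_spec("TssP", "linear_down", 30, amplitude = 2)
  )
}

#' Simulate an expression matrix with a known latent pseudotime
#'
#' Each cell receives a latent pseudotime `t ~ Uniform(0, 1)`. For a gene in
#' module `m`, log2 expression is
#' `baseline + amplitude * f_m(t) + Normal(0, noise_sd)`; background genes are
#' baseline plus noise only. Values are mapped to an FPKM-like scale by
#' `2^x - 1` truncated at zero, then Bernoulli dropout zeroes each
#' non-housekeeping entry with probability `dropout_rate`. Two housekeeping
#' genes (ACTB, GAPDH) are always expressed at a high baseline except in a
#' fraction `frac_failed_cells` of cells, where both are zeroed to emulate
#' failed libraries.
#'
#' @param n_cells Number of cells (>= 10).
#' @param modules List of [module_spec()] objects (non-empty).
#' @param n_background Number of background (pseudotime-independent) genes.
#' @param noise_sd Gaussian noise standard deviation in log2 units (>= 0).
#' @param dropout_rate Probability an entry is zeroed, in \[0, 1).
#' @param frac_failed_cells Fraction of cells with both housekeeping genes
#'   zeroed, in \[0, 1).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param baseline Baseline log2 expression of module/background genes.
#' @param hk_baseline Baseline log2 expression of the housekeeping genes.
#' @return A `synthetic_dataset`: list with elements `matrix` (genes x cells,
#'   FPKM-like), `true_pt` (tibble `cell_id`, `true_pt`), `module_map` (tibble
#'   `gene_id`, `module`), `gmt` (named list, one derived set per module) and
#'   `params`.
#' @export
simulate_expression <- function(n_cells, modules = default_modules(),
                                n_background = 100, noise_sd = 0.5,
                                dropout_rate = 0.1, frac_failed_cells = 0,
                                seed = 1L, baseline = 3, hk_baseline = 8) {
  assert_that(is_count(n_cells, min = 10L),
              "`n_cells` must be an integer >= 10: pseudotime on fewer cells is meaningless")
  assert_that(is.list(modules) && length(modules) > 0L, "`modules` must be a non-empty list")
  assert_that(all(vapply(modules, inherits, logical(1L), "module_spec")),
              "every element of `modules` must be a `module_spec`")
  mod_names <- vapply(modules, `[[`, character(1L), "name")
  assert_that(!anyDuplicated(mod_names), "module names must be unique")
  assert_that(is_count(n_background, min = 0L), "`n_background` must be a non-negative integer")
  assert_that(is_scalar_num(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  assert_that(is_scalar_num(dropout_rate) && dropout_rate >= 0 && dropout_rate < 1,
              "`dropout_rate` must be in [0, 1)")
  assert_that(is_scalar_num(frac_failed_cells) && frac_failed_cells >= 0 && frac_failed_cells < 1,
              "`frac_failed_cells` must be in [0, 1)")
  assert_that(is_count(seed, min = -Inf), "`seed` must be an integer")

  housekeeping <- c("ACTB", "GAPDH")
  withr::with_seed(as.integer(seed), {
    cell_ids <- sprintf("cell_%03d", seq_len(n_cells))
    t <- stats::runif(n_cells)

    gene_ids <- character(0L)
    module_of <- character(0L)
    log2_rows <- list()
    for (m in modules) {
      ids <- sprintf("%s_%03d", toupper(m$name), seq_len(m$n_genes))
      f <- shape_value(m$shape, t, onset = m$onset, steepness = m$steepness)
      block <- matrix(rep(baseline + m$amplitude * f, each = m$n_genes),
                      nrow = m$n_genes)
      gene_ids <- c(gene_ids, ids)
      module_of <- c(module_of, rep(m$name, m$n_genes))
      log2_rows[[m$name]] <- block
    }
    if (n_background > 0L) {
      ids <- sprintf("BG_%03d", seq_len(n_background))
      gene_ids <- c(gene_ids, ids)
      module_of <- c(module_of, rep("background", n_background))
      log2_rows[["background"]] <- matrix(baseline, nrow = n_background, ncol = n_cells)
    }
    gene_ids <- c(gene_ids, housekeeping)
    module_of <- c(module_of, rep("housekeeping", 2L))
    log2_rows[["housekeeping"]] <- matrix(hk_baseline, nrow = 2L, ncol = n_cells)

    assert_that(!anyDuplicated(gene_ids), "generated gene ids are not unique")
    x <- do.call(rbind, log2_rows)
    dimnames(x) <- list(gene_ids, cell_ids)
    if (noise_sd > 0) x <- x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow = nrow(x))

    fpkm <- pmax(2^x - 1, 0)
    if (dropout_rate > 0) {
      droppable <- !(rownames(fpkm) %in% housekeeping)
      keep <- matrix(stats::runif(sum(droppable) * n_cells) >= dropout_rate,
                     nrow = sum(droppable))
      fpkm[droppable, ] <- fpkm[droppable, , drop = FALSE] * keep
    }
    n_failed <- floor(frac_failed_cells * n_cells)
    failed <- character(0L)
    if (n_failed > 0L) {
      failed <- sample(cell_ids, n_failed)
      fpkm[housekeeping, failed] <- 0
    }

    gmt <- split(gene_ids, module_of)
    gmt <- gmt[setdiff(unique(module_of), c("background", "housekeeping"))]

    structure(
      list(
        matrix = fpkm,
        true_pt = tibble::tibble(cell_id = cell_ids, true_pt = t),
        module_map = tibble::tibble(gene_id = gene_ids, module = module_of),
        gmt = gmt,
        params = list(
          n_cells = as.integer(n_cells),
          modules = modules,
          n_background = as.integer(n_background),
          noise_sd = noise_sd, dropout_rate = dropout_rate,
          frac_failed_cells = frac_failed_cells, seed = as.integer(seed),
          baseline = baseline, hk_baseline = hk_baseline,
          housekeeping = housekeeping, failed_cells = sort(failed)
        )
      ),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf("<synthetic_dataset> %d genes x %d cells (%d modules, %d background, seed %d)\n",
              nrow(x$matrix), ncol(x$matrix), length(p$modules), p$n_background, p$seed))
  cat(sprintf("  noise_sd %.2g, dropout %.2g, failed cells %d\n",
              p$noise_sd, p$dropout_rate, length(p$failed_cells)))
  invisible(x)
}

#' Paper-like three-culture fixture
#'
#' Three independent synthetic datasets of 84, 54 and 77 cells, mirroring the
#' sizes of the three melanoma short-term cultures the pipeline was designed
#' around. All three carry the [default_modules()] programs; the third carries
#' the swapped MITF/AXL polarity (AXL-high late), so that the MITF-vs-AXL
#' geometry differs between cultures as it does between the BRAF- and
#' NRAS-mutant states.
#'
#' @param seed Integer base seed; each culture uses `seed + culture index`.
#' @param noise_sd,dropout_rate Passed to [simulate_expression()].
#' @return Named list of three `synthetic_dataset` objects
#'   (`wtwt`, `braf_mut`, `nras_mut`).
#' @export
paper_like_fixture <- function(seed = 1L, noise_sd = 0.5, dropout_rate = 0.1) {
  sizes <- c(wtwt = 84L, braf_mut = 54L, nras_mut = 77L)
  purrr::imap(as.list(sizes), function(n, nm) {
    simulate_expression(
      n_cells = n,
      modules = default_modules(axl_high = identical(nm, "nras_mut")),
      noise_sd = noise_sd, dropout_rate = dropout_rate,
      seed = as.integer(seed) + match(nm, names(sizes))
    )
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes the matrix as TSV and MatrixMarket, the derived gene sets as GMT,
#' the latent pseudotime as a two-column TSV and the generating parameters as
#' JSON.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  assert_that(inherits(dataset, "synthetic_dataset"), "`dataset` must be a synthetic_dataset")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(dataset$matrix, file.path(dir, "matrix.tsv"))
  write_expression_mtx(dataset$matrix, file.path(dir, "mtx"))
  write_gmt(dataset$gmt, file.path(dir, "modules.gmt"), description = "synthetic module")
  readr::write_tsv(dataset$true_pt, file.path(dir, "true_pt.tsv"), progress = FALSE)
  params <- dataset$params
  params$modules <- lapply(params$modules, unclass)
  jsonlite::write_json(params, file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
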