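# Shared fixture builders. Everything is generated in code at test time.

toy_matrix <- function(values, n_genes, n_cells,
                       genes = sprintf("g%02d", seq_len(n_genes)),
                       cells = sprintf("c%02d", seq_len(n_cells))) {
  matrix(values, nrow = n_genes, ncol = n_cells, dimnames = list(genes, cells))
}

quiet_std <- function(mat) suppressWarnings(log_standardize(mat))

# One monotone (decreasing) module plus background: the fixture for exact
# pseudotime-recovery checks.
monotone_dataset <- function(n_cells, noise_sd = 0, dropout_rate = 0, seed = 1) {
  simulate_expression(
    n_cells,
    modules = list(module_spec("stromal", "linear_down", 60, amplitude = 4)),
    n_background = 40, noise_sd = noise_sd, dropout_rate = dropout_rate,
    seed = seed
  )
}

# Full pipeline up to relative-activity profiles on one default-module
# culture, using inferred pseudotime.
fixture_profiles <- function(seed, axl_high = FALSE, n_cells = 84) {
  ds <- simulate_expression(n_cells, modules = default_modules(axl_high),
                            noise_sd = 0.5, dropout_rate = 0.1, seed = seed)
  std <- quiet_std(preprocess_matrix(ds$matrix))
  gsz <- suppressWarnings(score_gene_sets(std, ds$gmt))
  res <- infer_pseudotime(ds$matrix, ds$gmt$stromal, ds$gmt$cellcycle,
                          seed = seed, standardized = std)
  profile_signatures(gsz, res$pt)
}

# Analytic trajectory archetypes on a uniform pseudotime grid.
archetype_pair <- function(name, n = 101) {
  t <- seq(0, 1, length.out = n)
  ab <- switch(name,
    anti_diagonal = list(a = t, b = 1 - t),
    l_shape = list(a = pmin(2 * t, 1), b = pmax(2 * t - 1, 0)),
    orthogonal = list(a = t, b = 0.5 + 0.05 * cos(2 * pi * t)),
    arc = list(a = 0.5 * (1 - cos(pi * t)), b = sin(pi * t)),
    diagonal = list(a = t, b = t),
    bipolar = list(a = plogis(8 * (t - 0.5)), b = 1 - plogis(8 * (t - 0.5))),
    bipolar_flipped = list(a = 1 - plogis(8 * (t - 0.5)), b = plogis(8 * (t - 0.5))),
    stop("unknown archetype")
  )
  out <- tibble::tibble(pt = t, a = ab$a, b = ab$b)
  class(out) <- c("trajectory_pair", class(out))
  out
}
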