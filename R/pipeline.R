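#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the pipeline in one validated list; all values
#' are echoed into the provenance JSON of a run. `matrix` and `gmt` may be
#' file paths (TSV / GMT) or in-memory objects.
#'
#' @param matrix Genes x cells expression matrix, or path to a TSV.
#' @param gmt Named list of gene sets, or path to a GMT file.
#' @param out_dir Output directory of the run.
#' @param seed Integer seed (mandatory).
#' @param housekeeping Housekeeping gene ids for cell filtering.
#' @param stromal,proliferative Names of the anchor sets inside `gmt`.
#' @param k,l,n_graphs,metric Graph-ensemble parameters, see
#'   [build_knn_ensemble()].
#' @param span,degree LOESS parameters, see [loess_smooth()].
#' @param spline_df,fdr_threshold Association-test parameters, see
#'   [rank_targets()].
#' @param typology Thresholds from [typology_control()].
#' @param pairs Optional list of signature-name pairs to classify; defaults
#'   to all unordered pairs of scored sets.
#' @param filter If `FALSE`, the matrix is assumed pre-filtered (e.g. already
#'   cell-cycle corrected upstream).
#' @return A `run_config` list.
#' @export
run_config <- function(matrix, gmt, out_dir, seed,
                       housekeeping = c("ACTB", "GAPDH"),
                       stromal = "stromal", proliferative = "cellcycle",
                       k = 16, l = 8, n_graphs = 20,
                       metric = c("correlation", "euclidean"),
                       span = 0.5, degree = 1,
                       spline_df = 3L, fdr_threshold = 0.05,
                       typology = typology_control(),
                       pairs = NULL, filter = TRUE) {
  assert_that(!missing(seed) && is_count(seed, min = -Inf), "`seed` is mandatory and must be an integer")
  metric <- match.arg(metric)
  structure(
    list(matrix = matrix, gmt = gmt, out_dir = out_dir, seed = as.integer(seed),
         housekeeping = housekeeping, stromal = stromal, proliferative = proliferative,
         k = k, l = l, n_graphs = n_graphs, metric = metric,
         span = span, degree = degree,
         spline_df = spline_df, fdr_threshold = fdr_threshold,
         typology = typology, pairs = pairs, filter = filter),
    class = "run_config"
  )
}

pipeline_stage <- function(log, stage, expr) {
  t0 <- Sys.time()
  result <- tryCatch(expr, error = function(e) {
    stop_ptdyn(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log$lines <- c(log$lines, sprintf("%s\t%.3fs", stage, elapsed))
  list(result = result, log = log)
}

#' Run the full pseudotime-dynamics pipeline
#'
#' Preprocess (housekeeping filter + quantile normalization), standardize,
#' score all gene sets, infer pseudotime anchored on the stromal signature
#' and oriented by the proliferative one, detect the initial slow component,
#' smooth and rescale the signature profiles, rank sets by pseudotime
#' dependence and classify all requested biaxial trajectories. Every stage
#' output is written under `out_dir` together with a provenance JSON and a
#' run log; identical configuration and seed reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory stage results
#'   (`matrix`, `standardized`, `gsz`, `pseudotime`, `breakpoint`,
#'   `profiles`, `association`, `typology`) and the output directory.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"), "`config` must come from run_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(lines = character(0L))

  mat <- if (is.character(config$matrix)) read_expression_tsv(config$matrix) else config$matrix
  sets <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
  assert_that(config$stromal %in% names(sets),
              sprintf("stromal anchor set '%s' not in the collection", config$stromal))

  st <- pipeline_stage(log, "preprocess", preprocess_matrix(
    mat, housekeeping = config$housekeeping, filter = config$filter))
  norm <- st$result; log <- st$log
  st <- pipeline_stage(log, "standardize", suppressWarnings(log_standardize(norm)))
  std <- st$result; log <- st$log
  st <- pipeline_stage(log, "score", suppressWarnings(score_gene_sets(std, sets)))
  gsz <- st$result; log <- st$log

  st <- pipeline_stage(log, "pseudotime", {
    prolif <- if (!is.null(config$proliferative) && config$proliferative %in% names(sets)) {
      sets[[config$proliferative]]
    } else {
      NULL
    }
    infer_pseudotime(mat, stromal_genes = sets[[config$stromal]],
                     proliferative_genes = prolif,
                     k = config$k, l = config$l, n_graphs = config$n_graphs,
                     metric = config$metric, seed = config$seed,
                     standardized = std)
  })
  ptres <- st$result; log <- st$log

  st <- pipeline_stage(log, "breakpoint", detect_slow_component(ptres))
  brk <- st$result; log <- st$log

  st <- pipeline_stage(log, "profiles", profile_signatures(
    gsz, ptres$pt, span = config$span, degree = config$degree))
  profs <- st$result; log <- st$log

  st <- pipeline_stage(log, "associate", rank_targets(
    gsz, ptres$pt, spline_df = config$spline_df, fdr_threshold = config$fdr_threshold))
  assoc <- st$result; log <- st$log

  st <- pipeline_stage(log, "typology", {
    pairs <- config$pairs %||% utils::combn(names(sets), 2L, simplify = FALSE)
    classify_pairs(profs, pairs, control = config$typology)
  })
  typ <- st$result; log <- st$log

  # ---- outputs ----------------------------------------------------------
  out <- config$out_dir
  write_expression_tsv(norm, file.path(out, "normalized.tsv"))
  readr::write_tsv(gsz_table(gsz), file.path(out, "gsz.tsv"), progress = FALSE)
  write_pseudotime(ptres, out)
  readr::write_tsv(tibble::as_tibble(brk), file.path(out, "breakpoint.tsv"), progress = FALSE)
  write_profiles(profs, file.path(out, "profiles.tsv"))
  readr::write_tsv(tibble::as_tibble(assoc), file.path(out, "association.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(typ), file.path(out, "typology.tsv"), progress = FALSE)

  prov <- config
  prov$matrix <- if (is.character(config$matrix)) config$matrix else "<in-memory matrix>"
  prov$gmt <- if (is.character(config$gmt)) config$gmt else "<in-memory collection>"
  prov <- unclass(prov)
  prov$package_version <- as.character(utils::packageVersion("ptdyn"))
  prov$removed_cells <- removed_cells(norm)
  jsonlite::write_json(prov, file.path(out, "provenance.json"), auto_unbox = TRUE, digits = NA)
  readr::write_lines(c(sprintf("# ptdyn %s", prov$package_version), log$lines),
                     file.path(out, "run_log.tsv"))

  invisible(list(matrix = norm, standardized = std, gsz = gsz,
                 pseudotime = ptres, breakpoint = brk, profiles = profs,
                 association = assoc, typology = typ, out_dir = out))
}
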