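#' Read a gene-set collection from a GMT file
#'
#' GMT is tab-separated: set name, description, then one gene id per field.
#' Empty member fields are dropped; duplicate members within a set are kept
#' once.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors (one element per gene set), with
#'   a `source` attribute recording provenance.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) > 0L, "GMT file is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  assert_that(!any(bad), sprintf("GMT line(s) %s have fewer than 3 fields",
                                 paste(which(bad), collapse = ", ")))
  nms <- vapply(parts, `[[`, character(1L), 1L)
  assert_that(!anyDuplicated(nms), "GMT contains duplicated set names")
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)][nzchar(p[-c(1L, 2L)])]))
  assert_that(all(lengths(sets) > 0L), "GMT contains an empty gene set")
  names(sets) <- nms
  attr(sets, "source") <- path
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set (second GMT
#'   column); recycled.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "ptdyn") {
  assert_that(is.list(sets) && length(sets) > 0L && !is.null(names(sets)),
              "`sets` must be a non-empty named list")
  description <- rep_len(as.character(description), length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], description[[i]], sets[[i]]), collapse = "\t")
  }, character(1L))
  readr::write_lines(lines, path)
  invisible(path)
}
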