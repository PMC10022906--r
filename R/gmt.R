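#' Read and write gene sets in GMT format
#'
#' GMT is the tab-delimited gene-set interchange format: one set per line,
#' fields are set name, description, then member gene symbols.
#'
#' @param file path to a `.gmt` file.
#' @return `read_gmt()`: a named list of character vectors of gene symbols.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions,
#'   recycled; defaults to the set names.
#' @export
write_gmt <- function(sets, file, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("every gene set must be named")
  }
  descriptions <- descriptions %||% names(sets)
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(
    function(name, desc, genes) paste(c(name, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets
  )
  writeLines(lines, file)
  invisible(file)
}
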