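#' Probe-count container
#'
#' Bundles the raw probes-by-AOIs integer count matrix exported from a
#' digital spatial profiling run with its probe manifest. The manifest maps
#' every probe to a gene symbol and flags the no-target negative-control
#' probes whose counts estimate per-AOI background.
#'
#' @param counts integer matrix, probes x AOIs, with probe rownames and AOI
#'   colnames.
#' @param manifest tibble/data.frame with columns `probe_id`, `gene`,
#'   `is_negative`. Rows must cover every row of `counts`.
#' @return An object of class `probe_counts`: a list with elements `counts`
#'   and `manifest`.
#' @export
probe_counts <- function(counts, manifest) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric probes-by-AOIs matrix")
  }
  if (any(counts < 0)) abort("probe counts must be non-negative")
  manifest <- as_tibble(manifest)
  required <- c("probe_id", "gene", "is_negative")
  if (!all(required %in% names(manifest))) {
    abort(paste0(
      "manifest must have columns: ", paste(required, collapse = ", ")
    ))
  }
  if (is.null(rownames(counts))) abort("`counts` must carry probe rownames")
  if (is.null(colnames(counts))) abort("`counts` must carry AOI colnames")
  manifest <- manifest[match(rownames(counts), manifest$probe_id), ]
  if (anyNA(manifest$probe_id)) {
    abort("every row of `counts` must appear in the manifest")
  }
  if (!any(manifest$is_negative)) {
    abort("at least one negative-control probe is required")
  }
  bad <- !manifest$is_negative & (is.na(manifest$gene) | manifest$gene == "")
  if (any(bad)) {
    abort("every non-negative probe must map to exactly one gene symbol")
  }
  structure(list(counts = counts, manifest = manifest), class = "probe_counts")
}

#' @export
print.probe_counts <- function(x, ...) {
  n_neg <- sum(x$manifest$is_negative)
  cat(sprintf(
    "<probe_counts> %d probes (%d gene probes targeting %d genes, %d negative) x %d AOIs\n",
    nrow(x$counts), nrow(x$counts) - n_neg,
    length(unique(x$manifest$gene[!x$manifest$is_negative])),
    n_neg, ncol(x$counts)
  ))
  invisible(x)
}

#' @export
dim.probe_counts <- function(x) dim(x$counts)

# Split helper used throughout QC: gene-probe and negative-probe submatrices.
split_probes <- function(pc) {
  neg <- pc$manifest$is_negative
  list(
    gene = pc$counts[!neg, , drop = FALSE],
    negative = pc$counts[neg, , drop = FALSE],
    gene_map = pc$manifest$gene[!neg]
  )
}

#' Read and write the probe-level input files
#'
#' The on-disk interchange format is three tab-separated files: the probe
#' count matrix (first column `probe_id`, one column per AOI), the probe
#' manifest (`probe_id`, `gene`, `is_negative`) and the AOI annotation table
#' (`aoi_id`, `slide`, `subtype`, `grade`, `nuclei`, `area`).
#'
#' @param counts_file,manifest_file,annotation_file file paths.
#' @return `read_probe_dataset()`: list with `probe_counts` (a
#'   [probe_counts()] object) and `annotation` (tibble).
#' @export
read_probe_dataset <- function(counts_file, manifest_file, annotation_file) {
  raw <- readr::read_tsv(counts_file, comment = "#", show_col_types = FALSE)
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- raw[[1]]
  manifest <- readr::read_tsv(manifest_file, comment = "#", show_col_types = FALSE)
  annotation <- readr::read_tsv(annotation_file, comment = "#", show_col_types = FALSE)
  annotation$subtype <- as.character(annotation$subtype)
  annotation$grade <- as.character(annotation$grade)
  list(
    probe_counts = probe_counts(counts, manifest),
    annotation = as_tibble(annotation)
  )
}

#' @rdname read_probe_dataset
#' @param dataset list with elements `probe_counts` and `annotation`
#'   (and optionally `truth`), as produced by [simulate_dataset()].
#' @param dir output directory, created if missing.
#' @return `write_probe_dataset()`: the paths written, invisibly.
#' @export
write_probe_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pc <- dataset$probe_counts
  paths <- c(
    counts = file.path(dir, "probe_counts.tsv"),
    manifest = file.path(dir, "probe_manifest.tsv"),
    annotation = file.path(dir, "aoi_annotation.tsv")
  )
  counts_df <- tibble(probe_id = rownames(pc$counts))
  counts_df <- dplyr::bind_cols(counts_df, as_tibble(pc$counts))
  readr::write_tsv(counts_df, paths[["counts"]])
  readr::write_tsv(pc$manifest, paths[["manifest"]])
  readr::write_tsv(dataset$annotation, paths[["annotation"]])
  if (!is.null(dataset$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    jsonlite::write_json(dataset$truth, paths[["truth"]],
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(paths)
}

#' Write a gene expression matrix as TSV with a stage header
#'
#' The processing stage is recorded in a `#` comment line so downstream
#' stages can assert provenance without side-channel metadata.
#'
#' @param expr genes-by-AOIs matrix with a stage attribute.
#' @param file output path.
#' @export
write_expr_tsv <- function(expr, file) {
  assert_expr(expr)
  writeLines(sprintf("# stage: %s", expr_stage(expr)), file)
  df <- tibble(gene = rownames(expr))
  df <- dplyr::bind_cols(df, as_tibble(expr))
  readr::write_tsv(df, file, append = TRUE, col_names = TRUE)
  invisible(file)
}

#' @rdname write_expr_tsv
#' @param file path of a TSV written by [write_expr_tsv()].
#' @return `read_expr_tsv()`: the matrix with its stage attribute restored.
#' @export
read_expr_tsv <- function(file) {
  first <- readLines(file, n = 1L)
  stage <- sub("^# stage: ", "", first)
  df <- readr::read_tsv(file, comment = "#", show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (stage %in% EXPR_STAGES) m <- new_gene_expr(m, stage)
  m
}
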