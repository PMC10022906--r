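#' Subtract per-AOI background
#'
#' The geometric mean of an AOI's negative-probe counts estimates its
#' background level; it is subtracted from every collapsed gene value in
#' that AOI, flooring at zero.
#'
#' @param expr collapsed genes-by-AOIs matrix.
#' @param pc the [probe_counts()] object carrying the negative probes for
#'   the same AOIs.
#' @return Matrix at stage `background_subtracted`.
#' @export
subtract_background <- function(expr, pc) {
  assert_expr(expr, "collapsed_raw")
  neg <- split_probes(pc)$negative
  if (!all(colnames(expr) %in% colnames(neg))) {
    abort("negative probes are missing for some AOIs")
  }
  bg <- apply(neg[, colnames(expr), drop = FALSE], 2, geo_mean)
  out <- pmax(sweep(expr, 2, bg, `-`), 0)
  new_gene_expr(out, "background_subtracted")
}

#' Scale AOIs to counts per million
#'
#' Each AOI column is divided by its column total and multiplied by 1e6,
#' removing library-size differences.
#'
#' @param expr genes-by-AOIs matrix (background-subtracted).
#' @return Matrix at stage `scaled`; every column sums to 1e6.
#' @export
scale_library <- function(expr) {
  assert_expr(expr)
  totals <- colSums(expr)
  if (any(totals == 0)) {
    abort(paste0(
      "cannot scale all-zero AOI column(s): ",
      paste(colnames(expr)[totals == 0], collapse = ", ")
    ))
  }
  new_gene_expr(sweep(expr, 2, totals / 1e6, `/`), "scaled")
}

#' Quantile normalization
#'
#' Classic rank-based quantile normalization: sort each column, average
#' across columns at each rank, and map the averages back by each column's
#' original ranks. Afterwards every column carries the same multiset of
#' values (exactly so in the absence of ties). Tied values within a column
#' receive the mean of the rank-averaged values across their tied span, so
#' within-column rank order is preserved.
#'
#' @param expr genes-by-AOIs matrix with >= 2 AOIs.
#' @return Matrix at stage `quantile_normalized`.
#' @examples
#' m <- cbind(A = c(5, 3, 1), B = c(4, 6, 2))
#' rownames(m) <- paste0("g", 1:3)
#' dspipe:::new_gene_expr(m, "scaled") |> quantile_normalize()
#' @export
quantile_normalize <- function(expr) {
  assert_expr(expr)
  if (ncol(expr) < 2L) abort("quantile normalization requires >= 2 AOIs")
  srt <- vapply(seq_len(ncol(expr)), function(j) sort(expr[, j]),
    numeric(nrow(expr))
  )
  ref <- rowMeans(matrix(srt, nrow = nrow(expr)))
  out <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    v <- numeric(length(x))
    v[order(x)] <- ref
    # tied entries share the mean of the reference values over their span
    stats::ave(v, match(x, x), FUN = mean)
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr), dimnames = dimnames(expr))
  new_gene_expr(out, "quantile_normalized")
}

#' Log2 transform with pseudocount
#'
#' @param expr genes-by-AOIs matrix of non-negative values.
#' @param pseudocount added before the log (default 1, so 0 maps to 0).
#' @return Matrix at stage `log`, values `log2(x + pseudocount)`.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  assert_expr(expr)
  if (any(expr < 0)) abort("log transform requires non-negative values")
  new_gene_expr(log2(expr + pseudocount), "log")
}

#' Full normalization chain
#'
#' Applies, in fixed order: background subtraction, counts-per-million
#' scaling, quantile normalization, and log2 transform.
#'
#' @inheritParams subtract_background
#' @param pseudocount passed to [log_transform()].
#' @return Matrix at stage `log`.
#' @export
normalize_dsp <- function(expr, pc, pseudocount = 1) {
  expr |>
    subtract_background(pc) |>
    scale_library() |>
    quantile_normalize() |>
    log_transform(pseudocount = pseudocount)
}
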