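# shared helpers

#' Geometric mean with zero replacement
#'
#' Digital-counting convention: zeros are replaced by `zero_replace`
#' (default 1) before taking the geometric mean, so a single dropout probe
#' does not annihilate a gene's collapsed value.
#'
#' @param x non-negative numeric vector.
#' @param zero_replace value substituted for zeros before the log-mean.
#' @return The geometric mean as a length-1 numeric.
#' @examples
#' geo_mean(c(1, 4))   # 2
#' geo_mean(c(0, 8))   # sqrt(8)
#' @export
geo_mean <- function(x, zero_replace = 1) {
  if (length(x) == 0L) abort("cannot take the geometric mean of an empty vector")
  if (any(x < 0)) abort("geometric mean requires non-negative values")
  x[x == 0] <- zero_replace
  exp(mean(log(x)))
}

# Deterministic child seed for a named stochastic stage. All randomness in
# the package flows from one root seed through this map, so stages can be
# re-run independently yet reproducibly.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483587L)
}

# Expression-matrix stage bookkeeping -----------------------------------

EXPR_STAGES <- c(
  "collapsed_raw", "background_subtracted", "scaled",
  "quantile_normalized", "log"
)

new_gene_expr <- function(values, stage) {
  stopifnot(is.matrix(values), stage %in% EXPR_STAGES)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("gene expression matrix requires gene rownames and AOI colnames")
  }
  attr(values, "stage") <- stage
  values
}

#' Processing stage of an expression matrix
#'
#' @param expr a genes-by-AOIs matrix produced by [collapse_probes()] or a
#'   normalization step.
#' @return The stage tag, one of `collapsed_raw`, `background_subtracted`,
#'   `scaled`, `quantile_normalized`, `log`.
#' @export
expr_stage <- function(expr) attr(expr, "stage") %||% "unknown"

assert_expr <- function(expr, stages = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("expected a numeric genes-by-AOIs matrix")
  }
  if (!is.null(stages) && !expr_stage(expr) %in% stages) {
    warn(sprintf(
      "expression matrix is at stage '%s'; expected one of: %s",
      expr_stage(expr), paste(stages, collapse = ", ")
    ))
  }
  invisible(expr)
}

#' Convert an expression matrix to a long tibble
#'
#' @param expr genes-by-AOIs matrix.
#' @return Tibble with columns `gene`, `aoi_id`, `value`, `stage`.
#' @export
expr_tidy <- function(expr) {
  assert_expr(expr)
  tibble(
    gene = rep(rownames(expr), times = ncol(expr)),
    aoi_id = rep(colnames(expr), each = nrow(expr)),
    value = as.vector(expr),
    stage = expr_stage(expr)
  )
}
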