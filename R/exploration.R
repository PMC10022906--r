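#' Principal components analysis of AOIs
#'
#' AOIs are observations and genes variables; genes are centred and (by
#' default) scaled to unit variance before the decomposition.
#'
#' @param expr log genes-by-AOIs matrix with >= 2 AOIs and >= 2 genes.
#' @param n_components number of components to keep (default all).
#' @param scale. scale genes to unit variance (default TRUE). Constant
#'   genes are dropped with a warning when scaling.
#' @return Object of class `dsp_pca`: list with `scores` (tibble, one row
#'   per AOI), `loadings` (tibble, one row per gene), and `variance`
#'   (tibble: `component`, `variance_fraction`). Fractions are
#'   non-increasing and sum to at most 1.
#' @export
pca_aois <- function(expr, n_components = NULL, scale. = TRUE) {
  assert_expr(expr)
  if (ncol(expr) < 2) abort("PCA requires at least 2 AOIs")
  if (nrow(expr) < 2) abort("PCA requires at least 2 genes")
  x <- t(expr)
  if (scale.) {
    constant <- apply(x, 2, sd) == 0
    if (any(constant)) {
      warn(sprintf("dropping %d constant gene(s) before scaling", sum(constant)))
      x <- x[, !constant, drop = FALSE]
    }
  }
  fit <- prcomp(x, center = TRUE, scale. = scale.)
  k <- min(n_components %||% ncol(fit$x), ncol(fit$x))
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble(aoi_id = rownames(fit$x)),
        as_tibble(fit$x[, seq_len(k), drop = FALSE])
      ),
      loadings = dplyr::bind_cols(
        tibble(gene = rownames(fit$rotation)),
        as_tibble(fit$rotation[, seq_len(k), drop = FALSE])
      ),
      variance = tibble(
        component = colnames(fit$x)[seq_len(k)],
        variance_fraction = var_frac[seq_len(k)]
      )
    ),
    class = "dsp_pca"
  )
}

#' @export
print.dsp_pca <- function(x, ...) {
  cat(sprintf(
    "<dsp_pca> %d AOIs, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
    nrow(x$scores), nrow(x$variance),
    100 * x$variance$variance_fraction[1],
    if (nrow(x$variance) > 1) 100 * x$variance$variance_fraction[2] else NA
  ))
  invisible(x)
}

#' @export
tidy.dsp_pca <- function(x, ...) x$scores

#' @export
glance.dsp_pca <- function(x, ...) {
  tibble(
    n_aois = nrow(x$scores),
    n_components = nrow(x$variance),
    pc1_fraction = x$variance$variance_fraction[1],
    total_fraction = sum(x$variance$variance_fraction)
  )
}

#' Two-way hierarchical clustering for signature heatmaps
#'
#' Agglomerative clustering with Euclidean distance and the ward.D2
#' criterion (distances are not squared before the Ward update). For
#' heatmap use, rows can be z-scored across columns first; constant rows
#' z-score to 0 with a warning.
#'
#' @param values numeric matrix.
#' @param axis cluster `"rows"` or `"columns"`.
#' @param z_score z-score rows (per gene, across AOIs) before clustering.
#' @return List: `hclust` (stats::hclust object), `order` (item labels in
#'   dendrogram order), `values` (the matrix actually clustered).
#' @export
hierarchical_cluster <- function(values, axis = c("rows", "columns"),
                                 z_score = FALSE) {
  axis <- match.arg(axis)
  m <- as.matrix(values)
  if (z_score) {
    s <- apply(m, 1, sd)
    if (any(s == 0)) {
      warn(sprintf("%d constant row(s) z-scored to 0", sum(s == 0)))
    }
    m <- (m - rowMeans(m)) / ifelse(s == 0, 1, s)
  }
  items <- if (axis == "rows") m else t(m)
  if (nrow(items) < 2) abort("need at least 2 items to cluster")
  hc <- hclust(dist(items, method = "euclidean"), method = "ward.D2")
  list(hclust = hc, order = rownames(items)[hc$order], values = m)
}

#' Serialize a dendrogram as a Newick string
#'
#' @param clustering result of [hierarchical_cluster()] (or a bare hclust).
#' @param digits branch-length precision.
#' @return A Newick-format string (with terminating semicolon). Branch
#'   lengths follow the ultrametric convention that the tip-to-tip
#'   distance of two items equals their merge height.
#' @export
dendrogram_newick <- function(clustering, digits = 6) {
  hc <- if (inherits(clustering, "hclust")) clustering else clustering$hclust
  height_of <- function(node) if (node < 0) 0 else hc$height[node] / 2
  render <- function(node, parent_height) {
    len <- formatC(parent_height - height_of(node),
      digits = digits, format = "g"
    )
    if (node < 0) {
      paste0(hc$labels[-node], ":", len)
    } else {
      kids <- hc$merge[node, ]
      paste0(
        "(", render(kids[1], height_of(node)), ",",
        render(kids[2], height_of(node)), "):", len
      )
    }
  }
  root <- nrow(hc$merge)
  kids <- hc$merge[root, ]
  paste0(
    "(", render(kids[1], height_of(root)), ",",
    render(kids[2], height_of(root)), ");"
  )
}

#' Cut a dendrogram into k clusters
#'
#' @param clustering result of [hierarchical_cluster()] (or a bare hclust).
#' @param k number of clusters, `1 <= k <= n`.
#' @return Tibble: `item`, `cluster` (integer labels 1..k).
#' @export
cut_clusters <- function(clustering, k) {
  hc <- if (inherits(clustering, "hclust")) clustering else clustering$hclust
  n <- length(hc$labels %||% hc$order)
  if (k < 1 || k > n) abort(sprintf("k must be in [1, %d]", n))
  labels <- cutree(hc, k = k)
  tibble(item = names(labels), cluster = unname(labels))
}
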