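# Permutation-calibrated Spearman coexpression network.
#
# Edges connect gene pairs whose Spearman correlation is both strong
# (|rho| >= rho_min) and calibrated against a permutation null
# (q < q_max). The null pools |rho| values from permutations that shuffle
# each gene's expression values across AOIs, breaking all pairwise
# association while preserving gene marginals. q-values use the positive
# false-discovery-rate estimator with pi0 taken from the p-value
# distribution above lambda = 0.5.

#' Spearman correlation matrix of all genes
#'
#' @param expr log genes-by-AOIs matrix with >= 3 AOIs.
#' @return Symmetric genes-by-genes matrix of Spearman rho (average ranks
#'   for ties, diagonal 1). Constant genes yield `NA` rows/columns and are
#'   excluded from edge calling downstream.
#' @export
spearman_matrix <- function(expr) {
  assert_expr(expr)
  if (ncol(expr) < 3) abort("Spearman correlation requires >= 3 AOIs")
  constant <- apply(expr, 1, function(x) length(unique(x)) == 1L)
  rho <- suppressWarnings(cor(t(expr), method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- ifelse(constant, NA_real_, 1)
  rho
}

#' Permutation null distribution of Spearman correlations
#'
#' Each permutation shuffles gene expression values across AOIs, breaking
#' all gene-gene association while preserving each gene's marginal
#' distribution, and contributes the Spearman |rho| of `floor(genes / 2)`
#' disjoint random gene pairs. Pooling across permutations yields one
#' global null distribution of `n_perm * floor(genes / 2)` values, fine
#' enough to resolve small empirical p-values over all gene pairs.
#'
#' @param expr log genes-by-AOIs matrix.
#' @param n_perm number of permutations (default 10000, >= 1000).
#' @param seed RNG seed.
#' @return Object of class `dsp_null`: sorted numeric vector of null
#'   |rho| values with attributes `n_perm`, `n_aoi`, `seed`.
#' @export
permutation_null <- function(expr, n_perm = 10000, seed = 1L) {
  assert_expr(expr)
  if (n_perm < 1000) abort("n_perm must be at least 1000")
  n_aoi <- ncol(expr)
  if (n_aoi < 3) abort("permutation null requires >= 3 AOIs")
  # standardized ranks: rho(i, j) = sum(z_i * z_j) / (n - 1)
  ranks <- t(apply(expr, 1, rank))
  keep <- apply(ranks, 1, sd) > 0
  z <- ranks[keep, , drop = FALSE]
  z <- (z - rowMeans(z)) / apply(z, 1, sd)
  n_genes <- nrow(z)
  if (n_genes < 2) abort("need >= 2 non-constant genes for the null")
  half <- n_genes %/% 2
  set.seed(derive_seed(seed, "permutation_null"))
  vals <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    pairing <- sample.int(n_genes)
    left <- z[pairing[seq_len(half)], , drop = FALSE]
    # shuffling one member of each pair randomizes their relative order
    right <- z[pairing[half + seq_len(half)], sample.int(n_aoi), drop = FALSE]
    vals[[b]] <- abs(rowSums(left * right) / (n_aoi - 1))
  }
  vals <- sort(unlist(vals))
  structure(vals,
    n_perm = n_perm, n_aoi = n_aoi, seed = seed, class = "dsp_null"
  )
}

# Storey positive-FDR q-values; pi0 estimated from p-values above 0.5.
estimate_qvalues <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pi0 <- max(pi0, 1 / m) # guard against zero when all p are tiny
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o])
  pmin(q, 1)
}

#' Empirical p- and q-values for all gene pairs
#'
#' Per pair, the empirical p-value is
#' \eqn{(1 + \#\{|\rho_{null}| \ge |\rho|\}) / (1 + n_{null})}; q-values
#' follow from the positive-FDR estimator and are monotone in p.
#'
#' @param rho symmetric correlation matrix from [spearman_matrix()].
#' @param null a `dsp_null` object from [permutation_null()].
#' @return Tibble of unordered pairs: `gene_a`, `gene_b`, `rho`, `p_value`,
#'   `q_value`. Pairs with undefined correlation are omitted.
#' @export
edge_qvalues <- function(rho, null) {
  if (length(null) == 0) abort("null distribution is empty")
  genes <- rownames(rho)
  ut <- upper.tri(rho)
  idx <- which(ut & !is.na(rho), arr.ind = TRUE)
  r <- rho[cbind(idx[, 1], idx[, 2])]
  # null is sorted: count of null >= |r| by binary search
  n_null <- length(null)
  n_ge <- n_null - findInterval(abs(r) - 1e-12, null)
  p <- (1 + n_ge) / (1 + n_null)
  q <- estimate_qvalues(p)
  tibble(
    gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
    rho = r, p_value = p, q_value = q
  )
}

#' Build the thresholded coexpression network
#'
#' Computes the Spearman matrix and permutation null, then keeps edges
#' with `|rho| >= rho_min` and `q < q_max`. Edge weights are `rho^4`,
#' compressing moderate correlations while keeping weights in \[0, 1\].
#' Nodes are the genes incident to at least one passing edge.
#'
#' @param expr log genes-by-AOIs matrix.
#' @param rho_min absolute-correlation threshold (inclusive, default 0.7).
#' @param q_max q-value threshold (strict, default 0.01).
#' @param n_perm,seed passed to [permutation_null()].
#' @return Object of class `dsp_network`: list with `graph` (igraph),
#'   `edges` and `nodes` tibbles, `null`, and the thresholds used.
#'   An empty network (with a warning) when no pair passes.
#' @export
build_network <- function(expr, rho_min = 0.7, q_max = 0.01,
                          n_perm = 10000, seed = 1L) {
  rho <- spearman_matrix(expr)
  null <- permutation_null(expr, n_perm = n_perm, seed = seed)
  pairs <- edge_qvalues(rho, null)
  edges <- pairs |>
    filter(abs(.data$rho) >= rho_min, .data$q_value < q_max) |>
    mutate(weight = .data$rho^4)
  if (nrow(edges) == 0) {
    warn("no gene pair passes the edge thresholds; returning an empty network")
  }
  nodes <- tibble(gene = sort(unique(c(edges$gene_a, edges$gene_b))))
  graph <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "weight", "rho", "q_value")],
    directed = FALSE, vertices = nodes
  )
  structure(
    list(
      graph = graph, edges = edges, nodes = nodes, null = null,
      rho_min = rho_min, q_max = q_max, n_perm = n_perm, seed = seed
    ),
    class = "dsp_network"
  )
}

#' @export
print.dsp_network <- function(x, ...) {
  cat(sprintf(
    "<dsp_network> %d nodes, %d edges (|rho| >= %g, q < %g, %d permutations)\n",
    nrow(x$nodes), nrow(x$edges), x$rho_min, x$q_max, x$n_perm
  ))
  if ("cluster" %in% names(x$nodes)) {
    retained <- if ("retained" %in% names(x$nodes)) {
      x$nodes$retained
    } else {
      rep(TRUE, nrow(x$nodes))
    }
    cat(sprintf(
      "  %d Leiden clusters, %d retained (>= %s genes)\n",
      length(unique(x$nodes$cluster)),
      length(unique(x$nodes$cluster[retained])),
      attr(x$nodes, "min_size") %||% "?"
    ))
  }
  invisible(x)
}

#' @export
tidy.dsp_network <- function(x, ...) x$edges

#' @export
glance.dsp_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    rho_min = x$rho_min, q_max = x$q_max, n_perm = x$n_perm,
    n_clusters = if ("cluster" %in% names(x$nodes)) {
      length(unique(x$nodes$cluster))
    } else {
      NA_integer_
    }
  )
}

#' Leiden community detection on the coexpression network
#'
#' Runs the Leiden algorithm with a modularity quality function on the
#' rho^4-weighted undirected graph. The partition is seeded and therefore
#' reproducible.
#'
#' @param net a `dsp_network`.
#' @param resolution resolution parameter (default 0.5); larger values
#'   yield more, smaller communities.
#' @param seed RNG seed for the (stochastic) refinement phase.
#' @param n_iterations Leiden iterations (default 10).
#' @return The network with a `cluster` column added to `$nodes`.
#' @export
leiden_communities <- function(net, resolution = 0.5, seed = 1L,
                               n_iterations = 10) {
  stopifnot(inherits(net, "dsp_network"))
  if (nrow(net$nodes) == 0) abort("cannot cluster an empty network")
  set.seed(derive_seed(seed, "leiden"))
  cl <- igraph::cluster_leiden(
    net$graph,
    objective_function = "modularity",
    resolution = resolution, n_iterations = n_iterations,
    weights = igraph::E(net$graph)$weight
  )
  membership <- igraph::membership(cl)
  net$nodes$cluster <- sprintf("C%d", unname(membership[net$nodes$gene]))
  net$resolution <- resolution
  net
}

#' Flag clusters large enough for enrichment testing
#'
#' Clusters with fewer than `min_size` genes are flagged underpowered
#' (retained = FALSE) but keep their labels.
#'
#' @param net a clustered `dsp_network`.
#' @param min_size minimum cluster size (inclusive, default 10).
#' @return The network with a logical `retained` column on `$nodes`.
#' @export
filter_clusters <- function(net, min_size = 10) {
  stopifnot(inherits(net, "dsp_network"))
  if (!"cluster" %in% names(net$nodes)) {
    abort("run leiden_communities() before filter_clusters()")
  }
  sizes <- table(net$nodes$cluster)
  net$nodes$retained <- as.vector(sizes[net$nodes$cluster] >= min_size)
  attr(net$nodes, "min_size") <- min_size
  if (!any(net$nodes$retained) && nrow(net$nodes) > 0) {
    warn("all clusters fall below the minimum size; none retained")
  }
  net
}

#' Attach display overlays to network nodes
#'
#' Adds, per node: the z-scored (across genes) mean log expression within
#' each requested AOI group, the HGD-vs-LGD log2 fold change (node size in
#' the published layout), and membership flags for external gene sets.
#'
#' @param net a `dsp_network`.
#' @param expr log genes-by-AOIs matrix covering the network genes.
#' @param annotation AOI annotation tibble.
#' @param groups named list of expressions or `aoi_id` vectors defining
#'   AOI groups (as in [de_contrast()] selectors).
#' @param de optional `dsp_de` fit (e.g. HGD vs LGD) whose log2fc is
#'   attached as `log2fc`.
#' @param external_sets optional named list of gene sets; one logical
#'   membership column per set.
#' @return The network with overlay columns on `$nodes` and matching
#'   igraph vertex attributes.
#' @export
annotate_overlays <- function(net, expr, annotation, groups = list(),
                              de = NULL, external_sets = NULL) {
  stopifnot(inherits(net, "dsp_network"))
  assert_expr(expr)
  nodes <- net$nodes
  missing_genes <- setdiff(nodes$gene, rownames(expr))
  if (length(missing_genes)) {
    abort("expression matrix is missing network genes")
  }
  for (g in names(groups)) {
    sel <- groups[[g]]
    ids <- if (is.character(sel)) sel else annotation$aoi_id[sel]
    ids <- intersect(ids, colnames(expr))
    if (length(ids) == 0) abort(sprintf("unknown or empty AOI group '%s'", g))
    mu <- rowMeans(expr[nodes$gene, ids, drop = FALSE])
    z <- if (sd(mu) > 0) (mu - mean(mu)) / sd(mu) else mu * 0
    nodes[[paste0("z_", g)]] <- unname(z)
  }
  if (!is.null(de)) {
    tab <- tidy(de)
    nodes$log2fc <- tab$log2fc[match(nodes$gene, tab$gene)]
  }
  for (s in names(external_sets)) {
    nodes[[paste0("in_", s)]] <- nodes$gene %in% external_sets[[s]]
  }
  net$nodes <- nodes
  for (col in setdiff(names(nodes), "gene")) {
    net$graph <- igraph::set_vertex_attr(
      net$graph, col,
      index = nodes$gene, value = nodes[[col]]
    )
  }
  net
}

#' Export the network
#'
#' @param net a `dsp_network`.
#' @param edges_file TSV path for the edge list
#'   (`gene_a`, `gene_b`, `rho`, `q_value`, `weight`).
#' @param graphml_file optional GraphML path (written with node
#'   attributes via igraph).
#' @param clusters_file optional TSV path for node cluster membership.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, edges_file, graphml_file = NULL,
                          clusters_file = NULL) {
  readr::write_tsv(
    net$edges[, c("gene_a", "gene_b", "rho", "q_value", "weight")],
    edges_file
  )
  paths <- edges_file
  if (!is.null(graphml_file)) {
    igraph::write_graph(net$graph, graphml_file, format = "graphml")
    paths <- c(paths, graphml_file)
  }
  if (!is.null(clusters_file)) {
    readr::write_tsv(net$nodes, clusters_file)
    paths <- c(paths, clusters_file)
  }
  invisible(paths)
}
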