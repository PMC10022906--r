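log_mat <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("A%03d", seq_len(ncol(m)))
  dspipe:::new_gene_expr(m, "log")
}

test_that("Spearman matrix reproduces hand-computed coefficients", {
  m <- log_mat(rbind(
    a = c(1, 2, 3, 4),
    b = c(2, 1, 4, 3),
    c = c(10, 20, 30, 40),
    d = c(4, 3, 2, 1)
  ))
  rho <- spearman_matrix(m)
  expect_equal(rho["a", "c"], 1) # identical rank order
  expect_equal(rho["a", "d"], -1) # reversal
  expect_equal(rho["a", "b"], 0.6) # rank-difference formula by hand
  expect_true(isSymmetric(rho))
  expect_equal(unname(diag(rho)), rep(1, 4))
})

test_that("constant genes are recorded as missing and excluded from edges", {
  m <- log_mat(rbind(a = c(1, 2, 3), b = c(3, 1, 2), k = c(5, 5, 5)))
  rho <- spearman_matrix(m)
  expect_true(all(is.na(rho["k", ])))
  null <- permutation_null(m, n_perm = 1000, seed = 1)
  pairs <- edge_qvalues(rho, null)
  expect_false("k" %in% c(pairs$gene_a, pairs$gene_b))
})

test_that("the permutation null is seeded and matches the analytic Spearman null", {
  set.seed(15)
  m <- log_mat(matrix(rnorm(60 * 40), 60, 40))
  n1 <- permutation_null(m, n_perm = 1000, seed = 5)
  n2 <- permutation_null(m, n_perm = 1000, seed = 5)
  expect_identical(unclass(n1), unclass(n2))
  # analytic t-approximation oracle: |rho| ~ 95th percentile where the
  # two-sided t_{n-2} tail is 5%
  tcrit <- stats::qt(0.975, df = 38)
  rho_crit <- tcrit / sqrt(38 + tcrit^2)
  expect_equal(unname(quantile(n1, 0.95)), rho_crit, tolerance = 0.03)
})

test_that("empirical p-values are monotone in |rho| and q-values in p", {
  set.seed(16)
  m <- log_mat(matrix(rnorm(30 * 20), 30, 20))
  null <- permutation_null(m, n_perm = 1000, seed = 3)
  pairs <- edge_qvalues(spearman_matrix(m), null)
  o <- order(-abs(pairs$rho))
  expect_true(all(diff(pairs$p_value[o]) >= 0))
  expect_equal(which.min(pairs$q_value), which.max(abs(pairs$rho)))
  o2 <- order(pairs$p_value)
  expect_true(all(diff(pairs$q_value[o2]) >= -1e-12))
  # correlations below every null draw sit at p (and q) near 1
  weakest <- which.min(abs(pairs$rho))
  expect_gt(pairs$p_value[weakest], 0.9)
})

test_that("network edges respect both thresholds and rho^4 weights", {
  design <- two_grade_design(20, 20)
  cfg <- recovery_config(design,
    n_genes = 120, seed = 33,
    planted_subtype_genes = list(PB = list(n = 0, log2_effect = 0)),
    planted_hgd_genes = list(n = 0, log2_effect = 0),
    planted_modules = list(list(size = 15, loading = 1.5))
  )
  sim <- simulate_dataset(cfg)
  expr <- normalized_log_expr(sim)
  net <- build_network(expr, n_perm = 1000, seed = 33)
  expect_gt(nrow(net$edges), 0)
  expect_true(all(abs(net$edges$rho) >= 0.7))
  expect_true(all(net$edges$q_value < 0.01))
  expect_equal(net$edges$weight, net$edges$rho^4)
  expect_true(all(net$edges$gene_a != net$edges$gene_b))
  key <- paste(pmin(net$edges$gene_a, net$edges$gene_b),
    pmax(net$edges$gene_a, net$edges$gene_b)
  )
  expect_equal(anyDuplicated(key), 0)
  # nodes are exactly the genes incident to a passing edge
  expect_setequal(net$nodes$gene, unique(c(net$edges$gene_a, net$edges$gene_b)))
})

test_that("network construction is invariant to row and column order", {
  design <- two_grade_design(15, 15)
  cfg <- recovery_config(design,
    n_genes = 80, seed = 44,
    planted_subtype_genes = list(PB = list(n = 0, log2_effect = 0)),
    planted_hgd_genes = list(n = 0, log2_effect = 0),
    planted_modules = list(list(size = 12, loading = 1.5))
  )
  sim <- simulate_dataset(cfg)
  expr <- normalized_log_expr(sim)
  edge_key <- function(net) {
    sort(paste(
      pmin(net$edges$gene_a, net$edges$gene_b),
      pmax(net$edges$gene_a, net$edges$gene_b)
    ))
  }
  ref <- build_network(expr, n_perm = 1000, seed = 2)
  set.seed(1)
  shuffled <- dspipe:::new_gene_expr(
    expr[sample(nrow(expr)), sample(ncol(expr))], "log"
  )
  alt <- build_network(shuffled, n_perm = 1000, seed = 2)
  expect_equal(edge_key(alt), edge_key(ref))
})

test_that("an empty network is returned with a warning when nothing passes", {
  set.seed(17)
  m <- log_mat(matrix(rnorm(40 * 30), 40, 30))
  expect_warning(net <- build_network(m, n_perm = 1000, seed = 1), "no gene pair")
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$nodes), 0)
})

test_that("Leiden clustering separates disconnected cliques and handles singletons", {
  clique_edges <- function(genes) {
    pairs <- t(combn(genes, 2))
    tibble::tibble(
      gene_a = pairs[, 1], gene_b = pairs[, 2],
      rho = 0.9, p_value = 1e-4, q_value = 1e-4, weight = 0.9^4
    )
  }
  edges <- dplyr::bind_rows(
    clique_edges(sprintf("x%02d", 1:10)),
    clique_edges(sprintf("y%02d", 1:10))
  )
  nodes <- tibble::tibble(gene = sort(unique(c(edges$gene_a, edges$gene_b))))
  net <- structure(
    list(
      graph = igraph::graph_from_data_frame(edges, FALSE, nodes),
      edges = edges, nodes = nodes,
      rho_min = 0.7, q_max = 0.01, n_perm = 1000, seed = 1
    ),
    class = "dsp_network"
  )
  net <- leiden_communities(net, resolution = 0.5, seed = 1)
  expect_equal(length(unique(net$nodes$cluster)), 2)
  expect_equal(
    length(unique(net$nodes$cluster[startsWith(net$nodes$gene, "x")])), 1
  )
  # same seed, same labels
  again <- leiden_communities(net, resolution = 0.5, seed = 1)
  expect_identical(again$nodes$cluster, net$nodes$cluster)

  single <- structure(
    list(
      graph = igraph::make_empty_graph(1, directed = FALSE) |>
        igraph::set_vertex_attr("name", value = "solo"),
      edges = edges[0, ], nodes = tibble::tibble(gene = "solo"),
      rho_min = 0.7, q_max = 0.01, n_perm = 1000, seed = 1
    ),
    class = "dsp_network"
  )
  single <- leiden_communities(single, seed = 1)
  expect_equal(single$nodes$cluster, "C1")
})

test_that("Leiden recovers a planted partition", {
  set.seed(61)
  n_block <- 30
  rands <- sapply(1:5, function(s) {
    genes <- sprintf("g%02d", 1:(2 * n_block))
    block <- rep(1:2, each = n_block)
    pairs <- t(combn(seq_along(genes), 2))
    within <- block[pairs[, 1]] == block[pairs[, 2]]
    keep <- runif(nrow(pairs)) < ifelse(within, 0.9, 0.02)
    edges <- tibble::tibble(
      gene_a = genes[pairs[keep, 1]], gene_b = genes[pairs[keep, 2]],
      rho = 0.8, p_value = 1e-4, q_value = 1e-4, weight = 0.8^4
    )
    nodes <- tibble::tibble(gene = genes)
    net <- structure(
      list(
        graph = igraph::graph_from_data_frame(edges, FALSE, nodes),
        edges = edges, nodes = nodes,
        rho_min = 0.7, q_max = 0.01, n_perm = 1000, seed = s
      ),
      class = "dsp_network"
    )
    net <- leiden_communities(net, resolution = 0.5, seed = s)
    rand_index(net$nodes$cluster, block)
  })
  expect_true(all(rands >= 0.95))
})

test_that("cluster retention keeps >= 10 genes and flags the rest", {
  nodes <- tibble::tibble(
    gene = sprintf("g%02d", 1:19),
    cluster = rep(c("C1", "C2"), c(10, 9))
  )
  net <- structure(
    list(
      graph = igraph::make_empty_graph(0), edges = NULL, nodes = nodes,
      rho_min = 0.7, q_max = 0.01, n_perm = 1000, seed = 1
    ),
    class = "dsp_network"
  )
  out <- filter_clusters(net, min_size = 10)
  expect_true(all(out$nodes$retained[out$nodes$cluster == "C1"]))
  expect_false(any(out$nodes$retained[out$nodes$cluster == "C2"]))
  # all clusters small: zero retained, with a warning
  small <- net
  small$nodes$cluster <- rep(c("C1", "C2", "C3"), c(7, 6, 6))
  expect_warning(out2 <- filter_clusters(small, min_size = 10), "none retained")
  expect_false(any(out2$nodes$retained))
})

test_that("overlays carry group z-scores, fold changes, and set flags", {
  m <- log_mat(rbind(
    flat = rep(5, 6),
    up = c(1, 1, 1, 9, 9, 9),
    dn = c(9, 9, 9, 1, 1, 1)
  ))
  edges <- tibble::tibble(
    gene_a = c("flat", "up"), gene_b = c("up", "dn"),
    rho = c(0.8, 0.9), p_value = c(1e-4, 1e-4), q_value = c(1e-4, 1e-4),
    weight = c(0.8, 0.9)^4
  )
  nodes <- tibble::tibble(gene = c("dn", "flat", "up"))
  net <- structure(
    list(
      graph = igraph::graph_from_data_frame(edges, FALSE, nodes),
      edges = edges, nodes = nodes,
      rho_min = 0.7, q_max = 0.01, n_perm = 1000, seed = 1
    ),
    class = "dsp_network"
  )
  ann <- tibble::tibble(
    aoi_id = colnames(m), slide = "S01", subtype = "PB",
    grade = rep(c("LGD", "HGD"), each = 3)
  )
  de <- structure(
    list(table = tibble::tibble(
      gene = c("flat", "up", "dn"), log2fc = c(0, 3, -3)
    )),
    class = "dsp_de"
  )
  out <- annotate_overlays(net, m, ann,
    groups = list(hgd = ann$aoi_id[ann$grade == "HGD"]),
    de = de, external_sets = list(myset = c("up", "zz"))
  )
  z <- out$nodes$z_hgd
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_gt(z[out$nodes$gene == "up"], z[out$nodes$gene == "dn"])
  expect_equal(out$nodes$log2fc, c(-3, 0, 3))
  expect_equal(out$nodes$in_myset, c(FALSE, FALSE, TRUE))
  expect_error(
    annotate_overlays(net, m, ann, groups = list(bad = character(0))),
    "bad"
  )
})
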