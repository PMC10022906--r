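# Shared fixtures and small independent oracles.

# probe_counts object built directly from a counts matrix; probes named
# g* are gene probes (gene = probe id prefix before the final "_"), n*
# are negative probes.
make_pc <- function(counts) {
  is_neg <- grepl("^n", rownames(counts))
  gene <- ifelse(is_neg, NA_character_, sub("_[^_]*$", "", rownames(counts)))
  probe_counts(
    counts,
    tibble::tibble(
      probe_id = rownames(counts), gene = gene, is_negative = is_neg
    )
  )
}

# single-slide two-grade design for planted-effect benchmarks
two_grade_design <- function(n_hgd, n_lgd, subtype = "PB") {
  tibble::tibble(
    slide = rep(c("S01", "S02"), length.out = n_hgd + n_lgd),
    subtype = subtype,
    grade = rep(c("HGD", "LGD"), c(n_hgd, n_lgd))
  )
}

# balanced three-subtype design (GF forced LGD; PB/INT half HGD)
three_subtype_design <- function(n_per_subtype) {
  tibble::tibble(
    slide = rep(sprintf("S%02d", 1:6), length.out = 3 * n_per_subtype),
    subtype = rep(c("PB", "INT", "GF"), each = n_per_subtype),
    grade = c(
      rep(c("HGD", "LGD"), length.out = n_per_subtype),
      rep(c("HGD", "LGD"), length.out = n_per_subtype),
      rep("LGD", n_per_subtype)
    )
  )
}

# well-expressed regime used for planted-effect recovery benchmarks:
# genes comfortably above background so detection filtering keeps them
recovery_config <- function(design, n_genes, seed, probes_per_gene = 2, ...) {
  sim_config(
    design,
    n_genes = n_genes, probes_per_gene = probes_per_gene,
    baseline_log_mean = 6, gene_log_sd = 1,
    seed = seed, ...
  )
}

# collapse + normalize a simulated dataset without AOI/gene filtering
# (planted benchmarks control expression levels directly)
normalized_log_expr <- function(sim) {
  collapsed <- collapse_probes(sim$probe_counts)
  normalize_dsp(collapsed, sim$probe_counts)
}

# brute-force all-pairs Mann-Whitney AUC (ties count 1/2)
auc_bruteforce <- function(pos, neg) {
  wins <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(wins)
}

# brute-force Benjamini-Hochberg step-up
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Rand index of two labelings (pair-counting agreement)
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# weighted-KS running-sum enrichment score, written independently of the
# package implementation (cumsum keeps the accumulation in the same
# extended precision, so exact +/- ties in |run| resolve identically)
es_bruteforce <- function(stats_desc, hit) {
  n <- length(stats_desc)
  nr <- sum(abs(stats_desc[hit]))
  step <- vapply(seq_len(n), function(i) {
    if (hit[i]) abs(stats_desc[i]) / nr else -1 / (n - sum(hit))
  }, numeric(1))
  run <- cumsum(step)
  run[which.max(abs(run))]
}
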