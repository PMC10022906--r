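test_that("snAUC matches hand-enumerated pair counts", {
  expect_equal(compute_snauc(c(5, 6, 7), c(1, 2, 3)), 1.0)
  # 4 pairs: two wins, two losses
  expect_equal(compute_snauc(c(3, 1), c(2, 2)), 0.5)
  # 3 wins + 1 tie/2 = 3.5/4
  expect_equal(compute_snauc(c(2, 3), c(2, 1)), 0.875)
})

test_that("snAUC equals the all-pairs Mann-Whitney count on random instances", {
  set.seed(101)
  for (i in 1:50) {
    pos <- rpois(sample(2:30, 1), lambda = sample(1:20, 1))
    neg <- rpois(sample(2:30, 1), lambda = sample(1:20, 1))
    expect_equal(compute_snauc(pos, neg), auc_bruteforce(pos, neg))
  }
})

test_that("snAUC is invariant under joint strictly monotone transforms", {
  set.seed(7)
  pos <- rpois(20, 8)
  neg <- rpois(15, 4)
  base <- compute_snauc(pos, neg)
  expect_equal(compute_snauc(sqrt(pos), sqrt(neg)), base)
  expect_equal(compute_snauc(log1p(pos), log1p(neg)), base)
  expect_equal(compute_snauc(pos * 1000 + 3, neg * 1000 + 3), base)
})

test_that("snAUC rejects empty classes, naming the missing one", {
  expect_error(compute_snauc(numeric(0), 1:3), "gene")
  expect_error(compute_snauc(1:3, numeric(0)), "negative")
})

test_that("LOD follows the interpolated 90th-percentile convention", {
  expect_equal(compute_lod(rep(4, 75)), 4)
  expect_equal(compute_lod(rep(0, 75)), 0)
  # independent check of the type-7 quantile: h = 1 + 0.9 * (n - 1)
  x <- 1:10
  h <- 1 + 0.9 * 9
  lo <- floor(h)
  expected <- sort(x)[lo] + (h - lo) * (sort(x)[lo + 1] - sort(x)[lo])
  expect_equal(compute_lod(x), expected)
  expect_error(compute_lod(numeric(0)), "negative-probe")
})

test_that("detection is inclusive at the LOD, undetectable strictly below", {
  expect_true(is_detected(5, 5))
  expect_false(is_detected(4.9, 5))
  expect_true(is_detected(0, 0))
})

test_that("AOI filtering applies both criteria strictly and records reasons", {
  # A: clean separation but shallow; B: deep but no separation; C: good
  counts <- cbind(
    A = c(rep(9900, 10), rep(0, 5)),
    B = c(rep(10, 10), rep(10, 5)) * c(rep(5000, 10), rep(5000, 5)),
    C = c(rep(50000, 10), rep(10, 5))
  )
  rownames(counts) <- c(sprintf("g%02d_p1", 1:10), sprintf("n%02d", 1:5))
  pc <- make_pc(counts)
  res <- filter_aois(pc, min_counts = 100000, min_snauc = 0.65)
  expect_equal(colnames(res$probe_counts$counts), "C")
  qc <- res$qc
  expect_match(qc$reasons[qc$aoi_id == "A"], "low counts")
  expect_match(qc$reasons[qc$aoi_id == "B"], "low snAUC")
  expect_equal(qc$reasons[qc$aoi_id == "C"], "")

  # boundary: an AOI exactly at the snAUC threshold is removed (strict >)
  at_threshold <- qc$snauc[qc$aoi_id == "C"]
  expect_error(
    filter_aois(pc, min_counts = 100000, min_snauc = at_threshold),
    "no AOIs pass"
  )
  # boundary: exactly at the count threshold is removed
  expect_error(
    filter_aois(pc,
      min_counts = qc$total_counts[qc$aoi_id == "C"], min_snauc = 0.65
    ),
    "no AOIs pass"
  )
})

test_that("probe filtering removes only gene probes undetected in > 80% of AOIs", {
  n_aoi <- 10
  set.seed(3)
  # negatives all 4 -> LOD 4 in every AOI
  neg <- matrix(4, nrow = 5, ncol = n_aoi,
    dimnames = list(sprintf("n%02d", 1:5), NULL)
  )
  gene <- rbind(
    g01_p1 = c(rep(10, 2), rep(0, 8)), # undetected in 8/10 = 0.8, kept
    g02_p1 = c(rep(10, 1), rep(0, 9)), # undetected in 9/10 > 0.8, removed
    g03_p1 = rep(10, n_aoi) # always detected, kept
  )
  counts <- rbind(gene, neg)
  colnames(counts) <- sprintf("A%02d", 1:n_aoi)
  pc <- make_pc(counts)
  out <- filter_probes(pc, max_undetected_frac = 0.80)
  expect_setequal(
    rownames(out$counts),
    c("g01_p1", "g03_p1", sprintf("n%02d", 1:5))
  )
})

test_that("probe collapsing takes the zero-replaced geometric mean per gene", {
  counts <- rbind(
    g1_p1 = c(1, 2, 0), g1_p2 = c(4, 2, 8),
    g2_p1 = c(9, 2, 5),
    n1 = c(1, 1, 1)
  )
  colnames(counts) <- c("A", "B", "C")
  pc <- make_pc(counts)
  expr <- collapse_probes(pc)
  expect_equal(expr_stage(expr), "collapsed_raw")
  expect_equal(unname(expr["g1", ]), c(2, 2, sqrt(8)))
  expect_equal(unname(expr["g2", ]), c(9, 2, 5))
})

test_that("gene filtering keeps genes detected in at least 20% of AOIs", {
  n_aoi <- 100
  expr <- rbind(
    keep20 = c(rep(5, 20), rep(0, 80)),
    drop19 = c(rep(5, 19), rep(0, 81)),
    always = rep(5, n_aoi)
  )
  colnames(expr) <- sprintf("A%03d", seq_len(n_aoi))
  expr <- dspipe:::new_gene_expr(expr, "collapsed_raw")
  lods <- setNames(rep(5, n_aoi), colnames(expr))
  out <- filter_genes(expr, lods, min_detected_frac = 0.20)
  expect_setequal(rownames(out), c("keep20", "always"))
})

test_that("the QC chain is invariant to probe row order", {
  design <- two_grade_design(4, 4)
  cfg <- sim_config(design,
    n_genes = 60, probes_per_gene = 3, n_negative_probes = 12, seed = 21,
    planted_subtype_genes = list(PB = list(n = 0, log2_effect = 0)),
    planted_hgd_genes = list(n = 5, log2_effect = 2),
    planted_modules = list()
  )
  sim <- simulate_dataset(cfg)
  pc <- sim$probe_counts
  run_chain <- function(p) {
    fp <- filter_probes(p)
    filter_genes(collapse_probes(fp), aoi_lods(fp))
  }
  ref <- run_chain(pc)
  set.seed(1)
  perm <- sample(nrow(pc$counts))
  shuffled <- probe_counts(
    pc$counts[perm, , drop = FALSE], pc$manifest[perm, ]
  )
  expect_equal(run_chain(shuffled), ref)
})
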