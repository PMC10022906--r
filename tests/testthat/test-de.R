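log_expr <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("A%03d", seq_len(ncol(m)))
  dspipe:::new_gene_expr(m, "log")
}

two_group_annotation <- function(n_a, n_b) {
  tibble::tibble(
    aoi_id = sprintf("A%03d", seq_len(n_a + n_b)),
    slide = "S01",
    subtype = "PB",
    grade = rep(c("HGD", "LGD"), c(n_a, n_b))
  )
}

test_that("variance squeezing agrees with the limma empirical-Bayes estimator", {
  skip_if_not_installed("limma")
  set.seed(42)
  for (df in c(4, 10)) {
    s2 <- stats::rchisq(300, df) / df * exp(rnorm(300, 0, 0.8))
    ours <- squeeze_var(s2, df)
    theirs <- limma::squeezeVar(s2, df)
    expect_equal(ours$df_prior, theirs$df.prior, tolerance = 1e-4)
    expect_equal(ours$var_prior, theirs$var.prior, tolerance = 1e-4)
    expect_equal(ours$var_post, theirs$var.post, tolerance = 1e-6)
  }
})

test_that("moderated statistics agree with a limma two-group fit", {
  skip_if_not_installed("limma")
  set.seed(7)
  n_a <- 6
  n_b <- 5
  m <- matrix(rnorm(200 * (n_a + n_b), mean = 6), 200)
  expr <- log_expr(m)
  ann <- two_group_annotation(n_a, n_b)
  fit <- fit_contrast(expr, ann, de_contrast("t", grade == "HGD", grade == "LGD"))
  tab <- tidy(fit)

  dm <- cbind(1, rep(c(1, 0), c(n_a, n_b)))
  lfit <- limma::eBayes(limma::lmFit(m, dm))
  expect_equal(tab$log2fc, unname(lfit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(tab$t, unname(lfit$t[, 2]), tolerance = 1e-6)
  expect_equal(tab$p_value, unname(lfit$p.value[, 2]), tolerance = 1e-6)
})

test_that("with prior df forced to zero the fit reduces to ordinary t-tests", {
  set.seed(8)
  m <- matrix(rnorm(50 * 12, mean = 5), 50)
  expr <- log_expr(m)
  ann <- two_group_annotation(6, 6)
  fit <- fit_contrast(expr, ann,
    de_contrast("t", grade == "HGD", grade == "LGD"),
    prior_df = 0
  )
  tab <- tidy(fit)
  for (g in c(1, 17, 50)) {
    tt <- stats::t.test(m[g, 1:6], m[g, 7:12], var.equal = TRUE)
    expect_equal(tab$t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab$p_value[g], tt$p.value, tolerance = 1e-10)
  }
})

test_that("identical residual variances make the moderated t the ordinary t", {
  # every gene shares one residual pattern, so shrinkage is a no-op on t
  resid <- c(-1, 0.5, 0.5, -0.8, 0.3, 0.5, -1, 1, -0.5, 0)
  m <- t(sapply(1:20, function(g) g / 10 * rep(c(1, 0), each = 5) + resid))
  expr <- log_expr(m)
  ann <- two_group_annotation(5, 5)
  fit <- fit_contrast(expr, ann, de_contrast("t", grade == "HGD", grade == "LGD"))
  tab <- tidy(fit)
  ord_t <- sapply(1:20, function(g) {
    stats::t.test(m[g, 1:5], m[g, 6:10], var.equal = TRUE)$statistic
  })
  expect_equal(tab$t, unname(ord_t), tolerance = 1e-8)
})

test_that("swapping the groups negates fold changes and preserves p-values", {
  set.seed(10)
  expr <- log_expr(matrix(rnorm(80 * 10, mean = 4), 80))
  ann <- two_group_annotation(5, 5)
  ab <- tidy(fit_contrast(expr, ann, de_contrast("ab", grade == "HGD", grade == "LGD")))
  ba <- tidy(fit_contrast(expr, ann, de_contrast("ba", grade == "LGD", grade == "HGD")))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("degenerate inputs are rejected or handled without division by zero", {
  expr <- log_expr(matrix(rnorm(40), 10, 4))
  ann <- two_group_annotation(1, 3)
  expect_error(
    fit_contrast(expr, ann, de_contrast("t", grade == "HGD", grade == "LGD")),
    ">= 2"
  )
  # zero-variance genes get finite statistics through shrinkage
  m <- matrix(rnorm(40 * 8, mean = 5), 40)
  m[1, ] <- rep(c(3, 1), each = 4) # no within-group variance
  ann8 <- two_group_annotation(4, 4)
  fit <- fit_contrast(log_expr(m), ann8, de_contrast("t", grade == "HGD", grade == "LGD"))
  expect_true(all(is.finite(tidy(fit)$t)))
})

test_that("BH adjustment matches the closed form and validates input", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(20)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_bh(p), bh_bruteforce(p))
  }
})

test_that("DE calling applies strict thresholds on both axes", {
  tab <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    log2fc = c(1.5, 1.0, -2, 0.2),
    p_adj = c(0.01, 0.001, 0.04, 1e-9)
  )
  calls <- call_de(tab)
  expect_equal(calls$up, "a") # b excluded: log2fc not strictly > 1
  expect_equal(calls$down, "c")
})

test_that("subtype signatures are the pairwise intersections with provenance", {
  mk <- function(genes, fc) {
    structure(
      list(table = tibble::tibble(
        gene = genes, log2fc = fc,
        p_adj = rep(0.001, length(genes))
      )),
      class = "dsp_de"
    )
  }
  universe <- c("p1", "p2", "g1", "i1", "x1")
  pb_gf <- mk(universe, c(2, 2, -2, 0, 2)) # up: p1 p2 x1; down: g1
  pb_int <- mk(universe, c(2, 2, 0, -2, 0)) # up: p1 p2; down: i1
  int_gf <- mk(universe, c(0, 0, -2, 2, 0)) # up: i1; down: g1
  sigs <- build_subtype_signatures(pb_gf, pb_int, int_gf)
  expect_setequal(sigs$PB, c("p1", "p2")) # x1 in one contrast only
  expect_setequal(sigs$GF, "g1")
  expect_setequal(sigs$INT, "i1")
  expect_equal(nrow(sigs$union), 4)
  expect_false("x1" %in% sigs$union$gene)

  empty <- mk(character(0), numeric(0))
  sigs0 <- build_subtype_signatures(empty, empty, empty)
  expect_equal(lengths(sigs0[c("PB", "GF", "INT")]), c(PB = 0L, GF = 0L, INT = 0L))
})

test_that("external gene sets use the inclusive fold-change threshold", {
  tab <- tibble::tibble(
    gene = c("geneX", "geneY", "geneZ", "geneZ", "geneW"),
    log2fc = c(1.0, 0.9, 2, 2, -1.0),
    p_adj = c(0.01, 1e-9, 0.001, 0.001, 0.04)
  )
  sets <- build_external_gene_sets(tab, name = "cptac")
  expect_setequal(sets$cptac_up, c("geneX", "geneZ")) # 1.0 included, dup merged
  expect_equal(sets$cptac_down, "geneW")
  expect_error(build_external_gene_sets(tab[, 1:2]), "columns")
})

test_that("null simulations stay near the nominal false-call rate", {
  frac <- sapply(1:3, function(seed) {
    design <- two_grade_design(8, 8)
    cfg <- recovery_config(design,
      n_genes = 300, seed = seed,
      planted_subtype_genes = list(PB = list(n = 0, log2_effect = 0)),
      planted_hgd_genes = list(n = 0, log2_effect = 0),
      planted_modules = list()
    )
    sim <- simulate_dataset(cfg)
    expr <- normalized_log_expr(sim)
    fit <- fit_contrast(expr, sim$annotation,
      de_contrast("null", grade == "HGD", grade == "LGD")
    )
    mean(tidy(fit)$significant)
  })
  expect_lte(mean(frac), 0.05)
})
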