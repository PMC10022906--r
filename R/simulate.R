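#' Default 98-AOI cohort design
#'
#' A 12-slide design emulating the profiled cohort: six slides of
#' predominantly pancreaticobiliary (PB) histology and six of predominantly
#' intestinal (INT) histology, with interspersed gastric foveolar (GF)
#' regions that are uniformly low grade. The design carries 98 AOIs in
#' total, 50 high-grade (HGD) and 48 low-grade (LGD).
#'
#' @return Tibble with one row per AOI: columns `slide`, `subtype`, `grade`.
#' @export
default_cohort_design <- function() {
  slide_block <- function(slide, labels) {
    tibble(
      slide = slide,
      subtype = vapply(labels, `[[`, character(1), 1L),
      grade = vapply(labels, `[[`, character(1), 2L)
    )
  }
  pb <- c(
    rep(list(c("PB", "HGD")), 4),
    rep(list(c("PB", "LGD")), 2),
    rep(list(c("GF", "LGD")), 2)
  )
  int <- c(
    rep(list(c("INT", "HGD")), 4),
    rep(list(c("INT", "LGD")), 3),
    list(c("GF", "LGD"))
  )
  blocks <- c(
    list(slide_block("S01", c(pb, list(c("PB", "HGD"))))),
    lapply(2:6, function(i) slide_block(sprintf("S%02d", i), pb)),
    list(slide_block("S07", c(int, list(c("INT", "HGD"))))),
    lapply(8:12, function(i) slide_block(sprintf("S%02d", i), int))
  )
  bind_rows(blocks)
}

#' Simulation configuration
#'
#' Parameters of the negative-binomial probe-count generator. Counts are
#' drawn per probe around a gene-level mean
#' \eqn{2^{b_g + e_{ga} + o_a}} times a fixed per-probe multiplicative bias,
#' where \eqn{b_g} is the gene baseline (log2), \eqn{e_{ga}} collects planted
#' subtype/grade effects and module latent factors, and \eqn{o_a} is the
#' AOI library-size offset. Negative-control probes draw from a background
#' mean \eqn{2^{b_0 + o_a}} well below typical gene-probe means.
#'
#' @param design tibble with one row per AOI and columns `slide`, `subtype`
#'   (PB/INT/GF), `grade` (LGD/HGD). Defaults to [default_cohort_design()].
#' @param n_genes number of gene targets (default 1829).
#' @param probes_per_gene average probes per gene; genes receive
#'   \code{floor} or \code{ceiling} deterministically so the total probe
#'   count is `round(n_genes * probes_per_gene)` (default 4.694, i.e. 8584
#'   probes for 1829 genes).
#' @param n_negative_probes number of no-target control probes (default 75).
#' @param baseline_log_mean,gene_log_sd mean and sd (log2 scale) of gene
#'   baseline abundances.
#' @param background_log_mean log2 mean count of negative probes at the
#'   reference library size.
#' @param dispersion negative-binomial dispersion (1/size), shared across
#'   probes; must be > 0.
#' @param probe_bias_sd sdlog of the per-probe lognormal bias (geometric
#'   mean 1 within each gene, so geometric-mean collapsing is unbiased).
#' @param library_size_range length-2 positive vector; AOI library sizes
#'   are drawn uniformly in this range before confounding factors.
#' @param subtype_lib_factor,grade_lib_factor named multiplicative library
#'   factors emulating the higher cellular density (and hence yield) of
#'   INT/PB and HGD regions.
#' @param planted_subtype_genes named list (`PB`, `INT`, `GF`) of
#'   `list(n =, log2_effect =)`: genes upregulated in one subtype relative
#'   to both others.
#' @param planted_hgd_genes `list(n =, log2_effect =)`: genes upregulated
#'   in HGD relative to LGD AOIs, across subtypes.
#' @param planted_modules list of `list(size =, loading =)`: coexpression
#'   modules driven by a per-AOI latent factor with the given log2 loading.
#' @param seed root seed; every stochastic stage derives a child seed from
#'   it, so identical configurations reproduce identical datasets.
#' @return A validated `dsp_sim_config` list.
#' @export
sim_config <- function(design = default_cohort_design(),
                       n_genes = 1829L,
                       probes_per_gene = 8584 / 1829,
                       n_negative_probes = 75L,
                       baseline_log_mean = 2.9,
                       gene_log_sd = 1.8,
                       background_log_mean = 2.0,
                       dispersion = 0.15,
                       probe_bias_sd = 0.35,
                       library_size_range = c(40000, 1000000),
                       subtype_lib_factor = c(PB = 1.15, INT = 1.35, GF = 1),
                       grade_lib_factor = c(LGD = 1, HGD = 1.25),
                       planted_subtype_genes = list(
                         PB = list(n = 30, log2_effect = 2),
                         INT = list(n = 30, log2_effect = 2),
                         GF = list(n = 30, log2_effect = 2)
                       ),
                       planted_hgd_genes = list(n = 25, log2_effect = 2),
                       planted_modules = list(
                         list(size = 40, loading = 1.5),
                         list(size = 30, loading = 1.5),
                         list(size = 20, loading = 1.5)
                       ),
                       seed = 1L) {
  design <- as_tibble(design)
  if (!all(c("slide", "subtype", "grade") %in% names(design))) {
    abort("design must have columns slide, subtype, grade")
  }
  bad_subtype <- setdiff(unique(design$subtype), c("PB", "INT", "GF"))
  if (length(bad_subtype)) {
    abort(paste0("unknown subtype label(s): ", paste(bad_subtype, collapse = ", ")))
  }
  bad_grade <- setdiff(unique(design$grade), c("LGD", "HGD"))
  if (length(bad_grade)) {
    abort(paste0("unknown grade label(s): ", paste(bad_grade, collapse = ", ")))
  }
  gf_hgd <- design$subtype == "GF" & design$grade == "HGD"
  if (any(gf_hgd)) {
    abort("inconsistent design: GF/HGD AOIs requested, but GF epithelium is uniformly low grade")
  }
  stopifnot(
    n_genes >= 1, probes_per_gene >= 1, n_negative_probes >= 1,
    dispersion > 0, gene_log_sd >= 0, probe_bias_sd >= 0,
    length(library_size_range) == 2, all(library_size_range > 0),
    library_size_range[1] <= library_size_range[2]
  )
  planted <- c(
    unname(vapply(planted_subtype_genes, function(x) x$n, numeric(1))),
    planted_hgd_genes$n,
    vapply(planted_modules, function(x) x$size, numeric(1))
  )
  if (sum(planted) > n_genes) abort("more planted genes than genes available")
  effects <- c(
    vapply(planted_subtype_genes, function(x) x$log2_effect, numeric(1)),
    planted_hgd_genes$log2_effect,
    vapply(planted_modules, function(x) x$loading, numeric(1))
  )
  if (!all(is.finite(effects))) abort("planted effect sizes must be finite")
  structure(
    list(
      design = design, n_genes = as.integer(n_genes),
      probes_per_gene = probes_per_gene,
      n_negative_probes = as.integer(n_negative_probes),
      baseline_log_mean = baseline_log_mean, gene_log_sd = gene_log_sd,
      background_log_mean = background_log_mean, dispersion = dispersion,
      probe_bias_sd = probe_bias_sd,
      library_size_range = library_size_range,
      subtype_lib_factor = subtype_lib_factor,
      grade_lib_factor = grade_lib_factor,
      planted_subtype_genes = planted_subtype_genes,
      planted_hgd_genes = planted_hgd_genes,
      planted_modules = planted_modules,
      seed = as.integer(seed)
    ),
    class = "dsp_sim_config"
  )
}

#' Simulate a probe-count dataset with known ground truth
#'
#' Generates an overdispersed-count dataset with the structure the
#' downstream pipeline assumes: multiple probes per gene with fixed
#' multiplicative bias, no-target negative probes tracking per-AOI
#' background, library-size confounding by subtype and grade, and planted
#' subtype-specific genes, grade-associated genes, and latent-factor
#' coexpression modules.
#'
#' @param config a [sim_config()] object.
#' @return List of class `dsp_dataset` with elements:
#'   \describe{
#'     \item{probe_counts}{[probe_counts()] object, probes x AOIs.}
#'     \item{annotation}{tibble: `aoi_id`, `slide`, `subtype`, `grade`,
#'       `nuclei`, `area`.}
#'     \item{truth}{ground-truth ledger: planted gene memberships, per-AOI
#'       expected library scale, and the seed used.}
#'   }
#' @examples
#' design <- tibble::tibble(
#'   slide = "S01",
#'   subtype = rep("PB", 6),
#'   grade = rep(c("LGD", "HGD"), each = 3)
#' )
#' cfg <- sim_config(design,
#'   n_genes = 50, probes_per_gene = 2,
#'   n_negative_probes = 10, seed = 7
#' )
#' sim <- simulate_dataset(cfg)
#' dim(sim$probe_counts)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "dsp_sim_config")) {
    abort("`config` must be created by sim_config()")
  }
  design <- config$design
  n_aoi <- nrow(design)
  n_genes <- config$n_genes
  genes <- sprintf("G%04d", seq_len(n_genes))

  # AOI annotation: nuclei counts and surface areas
  set.seed(derive_seed(config$seed, "annotation"))
  slide_idx <- stats::ave(seq_len(n_aoi), design$slide, FUN = seq_along)
  aoi_id <- sprintf("%s_A%02d", design$slide, slide_idx)
  nuclei <- pmax(20L, as.integer(round(rlnorm(n_aoi, log(623), 0.55))))
  area <- round(nuclei * runif(n_aoi, 35, 65))
  annotation <- tibble(
    aoi_id = aoi_id, slide = design$slide,
    subtype = design$subtype, grade = design$grade,
    nuclei = nuclei, area = area
  )

  # gene baselines
  set.seed(derive_seed(config$seed, "genes"))
  baseline <- rnorm(n_genes, config$baseline_log_mean, config$gene_log_sd)

  # planted memberships: signature genes disjoint; modules disjoint from
  # each other and from the signatures
  set.seed(derive_seed(config$seed, "planted"))
  pool <- genes
  draw <- function(k) {
    picked <- sort(sample(pool, k))
    pool <<- setdiff(pool, picked)
    picked
  }
  subtype_sig <- lapply(config$planted_subtype_genes, function(x) draw(x$n))
  hgd_sig <- draw(config$planted_hgd_genes$n)
  modules <- lapply(config$planted_modules, function(x) draw(x$size))
  names(modules) <- sprintf("M%02d", seq_along(modules))

  # planted log2 effects per (gene, AOI)
  eff <- matrix(0, n_genes, n_aoi, dimnames = list(genes, aoi_id))
  for (s in names(subtype_sig)) {
    sel <- design$subtype == s
    if (any(sel) && length(subtype_sig[[s]])) {
      eff[subtype_sig[[s]], sel] <- eff[subtype_sig[[s]], sel] +
        config$planted_subtype_genes[[s]]$log2_effect
    }
  }
  if (length(hgd_sig)) {
    sel <- design$grade == "HGD"
    eff[hgd_sig, sel] <- eff[hgd_sig, sel] + config$planted_hgd_genes$log2_effect
  }
  set.seed(derive_seed(config$seed, "modules"))
  for (m in seq_along(modules)) {
    f <- rnorm(n_aoi)
    eff[modules[[m]], ] <- eff[modules[[m]], ] +
      config$planted_modules[[m]]$loading * rep(f, each = length(modules[[m]]))
  }

  # library-size offsets with density confounding
  set.seed(derive_seed(config$seed, "library"))
  lsr <- config$library_size_range
  lib <- runif(n_aoi, lsr[1], lsr[2]) *
    unname(config$subtype_lib_factor[design$subtype]) *
    unname(config$grade_lib_factor[design$grade])
  lib_ref <- sqrt(prod(lsr))
  offset <- log2(lib / lib_ref)

  # probe layout and fixed multiplicative biases
  n_probes_total <- round(n_genes * config$probes_per_gene)
  base_p <- floor(config$probes_per_gene)
  n_extra <- n_probes_total - base_p * n_genes
  probes_per_gene <- rep(base_p, n_genes) +
    as.integer(seq_len(n_genes) <= n_extra)
  gene_of_probe <- rep(genes, probes_per_gene)
  probe_id <- sprintf(
    "%s_P%02d", gene_of_probe,
    unlist(lapply(probes_per_gene, seq_len))
  )
  set.seed(derive_seed(config$seed, "probes"))
  bias <- rlnorm(length(probe_id), 0, config$probe_bias_sd)
  # centre biases to geometric mean 1 within each gene
  log_bias <- log(bias)
  centred <- log_bias - stats::ave(log_bias, gene_of_probe, FUN = mean)
  bias <- exp(centred)

  # counts
  set.seed(derive_seed(config$seed, "counts"))
  gene_row <- match(gene_of_probe, genes)
  log_mu <- sweep(eff[gene_row, , drop = FALSE], 2, offset, `+`) +
    baseline[gene_row]
  mu <- 2^log_mu * bias
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
    nrow = nrow(mu), dimnames = list(probe_id, aoi_id)
  )
  neg_id <- sprintf("NegPrb%02d", seq_len(config$n_negative_probes))
  neg_bias <- rlnorm(config$n_negative_probes, 0, config$probe_bias_sd)
  neg_mu <- outer(neg_bias, 2^(config$background_log_mean + offset))
  neg_counts <- matrix(
    rnbinom(length(neg_mu), mu = neg_mu, size = 1 / config$dispersion),
    nrow = config$n_negative_probes, dimnames = list(neg_id, aoi_id)
  )
  all_counts <- rbind(counts, neg_counts)
  storage.mode(all_counts) <- "integer"

  all_probe_ids <- c(probe_id, neg_id)
  manifest <- tibble(
    probe_id = all_probe_ids,
    gene = c(gene_of_probe, rep(NA_character_, config$n_negative_probes)),
    is_negative = c(
      rep(FALSE, length(gene_of_probe)),
      rep(TRUE, config$n_negative_probes)
    )
  )
  truth <- list(
    subtype_signatures = subtype_sig,
    hgd_signature = hgd_sig,
    modules = modules,
    library_scale = setNames(lib / lib_ref, aoi_id),
    seed = config$seed
  )
  structure(
    list(
      probe_counts = probe_counts(all_counts, manifest),
      annotation = annotation,
      truth = truth
    ),
    class = "dsp_dataset"
  )
}

#' @export
print.dsp_dataset <- function(x, ...) {
  cat("<dsp_dataset>\n")
  print(x$probe_counts)
  cat(sprintf(
    "  design: %d slides; %d HGD / %d LGD AOIs; planted: %d subtype, %d grade, %d module genes\n",
    length(unique(x$annotation$slide)),
    sum(x$annotation$grade == "HGD"), sum(x$annotation$grade == "LGD"),
    length(unlist(x$truth$subtype_signatures)),
    length(x$truth$hgd_signature), length(unlist(x$truth$modules))
  ))
  invisible(x)
}
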