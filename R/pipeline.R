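#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the published
#' defaults: AOI QC at >100,000 total counts and snAUC > 0.65; probe
#' filter at >80% undetected; gene filter at >= 20% detected; DE calling
#' at |log2FC| > 1 and P_adj < 0.05; network edges at |rho| >= 0.7 and
#' q < 0.01 calibrated on 10,000 permutations; Leiden resolution 0.5 with
#' rho^4 edge weights and a 10-gene minimum cluster size.
#'
#' @param counts_file,manifest_file,annotation_file input paths (ignored
#'   when `simulate` is supplied).
#' @param simulate optional [sim_config()]; when present the pipeline
#'   generates its input dataset and writes it under `out_dir/input/`.
#' @param out_dir output directory.
#' @param min_counts,min_snauc AOI QC thresholds.
#' @param max_undetected_frac probe-filter threshold.
#' @param min_detected_frac gene-filter threshold.
#' @param lfc,alpha DE thresholds.
#' @param gene_sets_file optional GMT path used for GSEA and cluster
#'   enrichment.
#' @param gsea_n_perm,gsea_min_size,gsea_max_size GSEA settings.
#' @param rho_min,q_max,network_n_perm,resolution,min_cluster network
#'   settings.
#' @param seed root seed for every stochastic stage.
#' @return A validated `dsp_pipeline_config` list.
#' @export
pipeline_config <- function(counts_file = NULL, manifest_file = NULL,
                            annotation_file = NULL, simulate = NULL,
                            out_dir = "dspipe_out",
                            min_counts = 100000, min_snauc = 0.65,
                            max_undetected_frac = 0.80,
                            min_detected_frac = 0.20,
                            lfc = 1.0, alpha = 0.05,
                            gene_sets_file = NULL,
                            gsea_n_perm = 1000, gsea_min_size = 5,
                            gsea_max_size = 500,
                            rho_min = 0.7, q_max = 0.01,
                            network_n_perm = 10000, resolution = 0.5,
                            min_cluster = 10, seed = 1L) {
  if (!is.null(simulate) && !inherits(simulate, "dsp_sim_config")) {
    abort("`simulate` must be a sim_config() object")
  }
  checks <- list(
    min_counts = min_counts >= 0,
    min_snauc = min_snauc >= 0 && min_snauc <= 1,
    max_undetected_frac = max_undetected_frac >= 0 && max_undetected_frac <= 1,
    min_detected_frac = min_detected_frac >= 0 && min_detected_frac <= 1,
    lfc = lfc >= 0, alpha = alpha > 0 && alpha <= 1,
    gsea_n_perm = gsea_n_perm >= 100,
    rho_min = rho_min >= 0 && rho_min <= 1,
    q_max = q_max > 0 && q_max <= 1,
    network_n_perm = network_n_perm >= 1000,
    resolution = resolution > 0,
    min_cluster = min_cluster >= 1
  )
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad)) {
    abort(paste0("invalid configuration value(s): ", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      counts_file = counts_file, manifest_file = manifest_file,
      annotation_file = annotation_file, simulate = simulate,
      out_dir = out_dir,
      min_counts = min_counts, min_snauc = min_snauc,
      max_undetected_frac = max_undetected_frac,
      min_detected_frac = min_detected_frac,
      lfc = lfc, alpha = alpha,
      gene_sets_file = gene_sets_file,
      gsea_n_perm = gsea_n_perm, gsea_min_size = gsea_min_size,
      gsea_max_size = gsea_max_size,
      rho_min = rho_min, q_max = q_max,
      network_n_perm = network_n_perm, resolution = resolution,
      min_cluster = min_cluster, seed = as.integer(seed)
    ),
    class = "dsp_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate:` block (keys mirroring [sim_config()], minus the design) may
#' request synthetic input.
#'
#' @param file YAML path.
#' @return A `dsp_pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  y <- yaml::read_yaml(file)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    if (!is.null(sim_args$library_size_range)) {
      sim_args$library_size_range <- as.numeric(sim_args$library_size_range)
    }
    sim <- do.call(sim_config, sim_args)
    y$simulate <- NULL
  }
  do.call(pipeline_config, c(y, list(simulate = sim)))
}

pipeline_stages <- c(
  "simulate", "qc", "normalize", "de", "signatures",
  "gsea", "network", "explore"
)

# Canonical six pairwise subgroup comparisons over slide-predominant
# subtype x grade. The predominant subtype of a slide is the most common
# non-GF subtype among its AOIs, so GF AOIs fall into the low-grade arm of
# their slide's predominant subtype.
subgroup_labels <- function(annotation) {
  pred <- annotation |>
    filter(.data$subtype != "GF") |>
    group_by(.data$slide) |>
    summarise(
      predominant = names(sort(table(.data$subtype), decreasing = TRUE))[1]
    )
  annotation |>
    left_join(pred, by = "slide") |>
    mutate(subgroup = paste(.data$predominant, .data$grade, sep = "-"))
}

#' Run the analysis pipeline
#'
#' Executes, in order: simulate (optional), QC and filtering,
#' normalization, differential expression (grade, three subtype pairwise
#' contrasts, and the six pairwise subgroup comparisons), signature
#' construction, preranked GSEA, the permutation-calibrated coexpression
#' network with Leiden communities and cluster enrichment, and the
#' unsupervised views (PCA, two-way signature clustering with a k = 2
#' risk cut). Each stage writes its tables under `out_dir` and records its
#' input/output dimensions in `manifest.json`. Identical configurations
#' produce byte-identical outputs.
#'
#' @param config a `dsp_pipeline_config`.
#' @param stages character subset of stages to run (default all);
#'   prerequisites of a requested stage are loaded from `out_dir` when not
#'   run in the same call.
#' @return The run manifest (named list), invisibly.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  stopifnot(inherits(config, "dsp_pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_file <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_file)) {
    jsonlite::read_json(manifest_file)
  } else {
    list(
      package = "dspipe",
      version = as.character(utils::packageVersion("dspipe")),
      seed = config$seed,
      parameters = config[setdiff(names(config), c(
        "counts_file", "manifest_file", "annotation_file", "simulate", "out_dir"
      ))],
      stages = list()
    )
  }
  state <- new.env(parent = emptyenv())
  fail <- function(stage, msg) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, msg))
  }

  load_dataset <- function() {
    if (!is.null(state$dataset)) {
      return(state$dataset)
    }
    in_dir <- file.path(out, "input")
    if (!is.null(config$simulate) && file.exists(file.path(in_dir, "probe_counts.tsv"))) {
      ds <- read_probe_dataset(
        file.path(in_dir, "probe_counts.tsv"),
        file.path(in_dir, "probe_manifest.tsv"),
        file.path(in_dir, "aoi_annotation.tsv")
      )
    } else if (!is.null(config$counts_file)) {
      ds <- read_probe_dataset(
        config$counts_file, config$manifest_file, config$annotation_file
      )
    } else {
      fail("input", "no input files configured and no simulated input found")
    }
    state$dataset <- ds
    ds
  }
  load_expr <- function(stage_file, slot) {
    if (!is.null(state[[slot]])) {
      return(state[[slot]])
    }
    f <- file.path(out, stage_file)
    if (!file.exists(f)) fail(slot, paste0("missing intermediate ", f))
    state[[slot]] <- read_expr_tsv(f)
    state[[slot]]
  }
  load_de <- function(name) {
    if (!is.null(state$de[[name]])) {
      return(state$de[[name]])
    }
    f <- file.path(out, "de", paste0(name, ".tsv"))
    if (!file.exists(f)) fail("de", paste0("missing DE table ", f))
    readr::read_tsv(f, comment = "#", show_col_types = FALSE)
  }

  if ("simulate" %in% stages && !is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate)
    write_probe_dataset(sim, file.path(out, "input"))
    state$dataset <- sim
    manifest$stages$simulate <- list(
      n_probes = nrow(sim$probe_counts$counts),
      n_aois = ncol(sim$probe_counts$counts),
      n_genes = config$simulate$n_genes
    )
  }

  if ("qc" %in% stages) {
    ds <- load_dataset()
    aoi_res <- filter_aois(ds$probe_counts,
      min_counts = config$min_counts, min_snauc = config$min_snauc
    )
    pc <- filter_probes(aoi_res$probe_counts,
      max_undetected_frac = config$max_undetected_frac
    )
    collapsed <- collapse_probes(pc)
    lods <- aoi_lods(pc)
    filtered <- filter_genes(collapsed, lods,
      min_detected_frac = config$min_detected_frac
    )
    jsonlite::write_json(
      aoi_res$qc, file.path(out, "qc_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_expr_tsv(filtered, file.path(out, "gene_counts.tsv"))
    state$pc <- pc
    state$collapsed <- filtered
    manifest$stages$qc <- list(
      aois_in = nrow(aoi_res$qc), aois_pass = sum(aoi_res$qc$pass),
      probes_kept = nrow(pc$counts),
      genes_collapsed = nrow(collapsed), genes_kept = nrow(filtered)
    )
  }

  if ("normalize" %in% stages) {
    collapsed <- load_expr("gene_counts.tsv", "collapsed")
    if (is.null(state$pc)) {
      ds <- load_dataset()
      state$pc <- probe_counts(
        ds$probe_counts$counts[, colnames(collapsed), drop = FALSE],
        ds$probe_counts$manifest
      )
    }
    normalized <- normalize_dsp(collapsed, state$pc)
    write_expr_tsv(normalized, file.path(out, "gene_expression_log.tsv"))
    state$normalized <- normalized
    manifest$stages$normalize <- list(
      genes = nrow(normalized), aois = ncol(normalized), stage = "log"
    )
  }

  if ("de" %in% stages) {
    expr <- load_expr("gene_expression_log.tsv", "normalized")
    ann <- load_dataset()$annotation
    ann <- subgroup_labels(ann[ann$aoi_id %in% colnames(expr), ])
    contrasts <- list(
      HGD_vs_LGD = de_contrast("HGD_vs_LGD", grade == "HGD", grade == "LGD"),
      PB_vs_GF = de_contrast("PB_vs_GF", subtype == "PB", subtype == "GF"),
      PB_vs_INT = de_contrast("PB_vs_INT", subtype == "PB", subtype == "INT"),
      INT_vs_GF = de_contrast("INT_vs_GF", subtype == "INT", subtype == "GF")
    )
    subgroups <- sort(unique(ann$subgroup))
    combos <- combn(subgroups, 2, simplify = FALSE)
    # bind the subgroup labels in a fresh environment per contrast so the
    # captured quosures do not all see the final loop value
    make_sub_contrast <- function(nm, hi, lo) {
      de_contrast(nm, subgroup == hi, subgroup == lo)
    }
    for (cmb in combos) {
      nm <- paste0(gsub("-", "", cmb[2]), "_vs_", gsub("-", "", cmb[1]))
      contrasts[[nm]] <- make_sub_contrast(nm, cmb[2], cmb[1])
    }
    dir.create(file.path(out, "de"), showWarnings = FALSE)
    state$de <- list()
    de_dims <- list()
    for (nm in names(contrasts)) {
      fit <- tryCatch(
        fit_contrast(expr, ann, contrasts[[nm]],
          lfc = config$lfc, alpha = config$alpha
        ),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        fail("de", paste0(nm, ": ", conditionMessage(fit)))
      }
      readr::write_tsv(tidy(fit), file.path(out, "de", paste0(nm, ".tsv")))
      state$de[[nm]] <- tidy(fit)
      de_dims[[nm]] <- sum(tidy(fit)$significant)
    }
    manifest$stages$de <- de_dims
  }

  if ("signatures" %in% stages) {
    expr <- load_expr("gene_expression_log.tsv", "normalized")
    ann <- load_dataset()$annotation
    ann <- ann[ann$aoi_id %in% colnames(expr), ]
    need <- c("PB_vs_GF", "PB_vs_INT", "INT_vs_GF", "HGD_vs_LGD")
    tabs <- lapply(need, load_de)
    names(tabs) <- need
    as_fit <- function(tab, nm) {
      structure(list(table = tab, contrast = nm), class = "dsp_de")
    }
    sigs <- build_subtype_signatures(
      as_fit(tabs$PB_vs_GF, "PB_vs_GF"),
      as_fit(tabs$PB_vs_INT, "PB_vs_INT"),
      as_fit(tabs$INT_vs_GF, "INT_vs_GF"),
      lfc = config$lfc, alpha = config$alpha
    )
    hgd <- call_de(tabs$HGD_vs_LGD, lfc = config$lfc, alpha = config$alpha)
    write_gmt(
      list(
        subtype_PB = sigs$PB, subtype_GF = sigs$GF, subtype_INT = sigs$INT,
        hgd_up = hgd$up, hgd_down = hgd$down
      ),
      file.path(out, "signatures.gmt")
    )
    readr::write_tsv(sigs$union, file.path(out, "subtype_signature_union.tsv"))
    state$signatures <- sigs
    state$hgd_signature <- hgd
    manifest$stages$signatures <- list(
      PB = length(sigs$PB), GF = length(sigs$GF), INT = length(sigs$INT),
      union = nrow(sigs$union),
      hgd_up = length(hgd$up), hgd_down = length(hgd$down)
    )
  }

  if ("gsea" %in% stages) {
    if (is.null(config$gene_sets_file)) {
      manifest$stages$gsea <- list(skipped = "no gene_sets_file configured")
    } else {
      sets <- read_gmt(config$gene_sets_file)
      de_files <- list.files(file.path(out, "de"), pattern = "\\.tsv$")
      if (length(de_files) == 0) fail("gsea", "no DE tables found; run the de stage first")
      analyses <- sub("\\.tsv$", "", de_files)
      res <- bind_rows(lapply(analyses, function(nm) {
        tab <- load_de(nm)
        ranked <- tibble(gene = tab$gene, stat = tab$log2fc)
        r <- suppressWarnings(gsea_preranked(
          ranked, sets,
          n_perm = config$gsea_n_perm,
          min_size = config$gsea_min_size, max_size = config$gsea_max_size,
          seed = derive_seed(config$seed, paste0("gsea_", nm))
        ))
        r$analysis <- nm
        r
      }))
      res$leading_edge <- vapply(
        res$leading_edge, paste, character(1), collapse = ","
      )
      readr::write_tsv(
        res[, c(
          "analysis", "set", "size", "es", "nes", "p_value", "p_adj",
          "leading_edge"
        )],
        file.path(out, "gsea.tsv")
      )
      manifest$stages$gsea <- list(
        analyses = length(analyses), sets_tested = length(unique(res$set))
      )
    }
  }

  if ("network" %in% stages) {
    expr <- load_expr("gene_expression_log.tsv", "normalized")
    ann <- load_dataset()$annotation
    ann <- subgroup_labels(ann[ann$aoi_id %in% colnames(expr), ])
    net <- build_network(expr,
      rho_min = config$rho_min, q_max = config$q_max,
      n_perm = config$network_n_perm,
      seed = derive_seed(config$seed, "network")
    )
    if (nrow(net$nodes) > 0) {
      net <- leiden_communities(net,
        resolution = config$resolution,
        seed = derive_seed(config$seed, "leiden")
      )
      net <- filter_clusters(net, min_size = config$min_cluster)
      hgd_tab <- load_de("HGD_vs_LGD")
      groups <- split(ann$aoi_id, ann$subgroup)
      ext <- if (!is.null(config$gene_sets_file)) {
        read_gmt(config$gene_sets_file)
      } else {
        NULL
      }
      net <- annotate_overlays(net, expr, ann,
        groups = groups,
        de = structure(list(table = hgd_tab), class = "dsp_de"),
        external_sets = ext
      )
      if (!is.null(ext)) {
        retained <- unique(net$nodes$cluster[net$nodes$retained])
        enr <- bind_rows(lapply(sort(retained), function(cl) {
          r <- hypergeometric_enrich(
            net$nodes$gene[net$nodes$cluster == cl], ext, rownames(expr)
          )
          r$cluster <- cl
          r
        }))
        if (nrow(enr)) {
          readr::write_tsv(
            enr[, c("cluster", "set", "set_size", "overlap", "p_value", "p_adj")],
            file.path(out, "cluster_enrichment.tsv")
          )
        }
      }
    }
    write_network(net,
      edges_file = file.path(out, "network_edges.tsv"),
      graphml_file = file.path(out, "network.graphml"),
      clusters_file = file.path(out, "network_nodes.tsv")
    )
    retained_cl <- if ("retained" %in% names(net$nodes)) {
      length(unique(net$nodes$cluster[net$nodes$retained]))
    } else {
      0L
    }
    manifest$stages$network <- list(
      nodes = nrow(net$nodes), edges = nrow(net$edges),
      clusters = if ("cluster" %in% names(net$nodes)) {
        length(unique(net$nodes$cluster))
      } else {
        0L
      },
      clusters_retained = retained_cl
    )
    state$network <- net
  }

  if ("explore" %in% stages) {
    expr <- load_expr("gene_expression_log.tsv", "normalized")
    pca <- pca_aois(expr)
    readr::write_tsv(pca$scores, file.path(out, "pca_scores.tsv"))
    readr::write_tsv(pca$variance, file.path(out, "pca_variance.tsv"))
    risk <- NULL
    sig_file <- file.path(out, "signatures.gmt")
    if (file.exists(sig_file)) {
      sigs <- read_gmt(sig_file)
      hgd_genes <- intersect(
        unique(c(sigs$hgd_up, sigs$hgd_down)), rownames(expr)
      )
      if (length(hgd_genes) >= 2) {
        hc <- hierarchical_cluster(expr[hgd_genes, , drop = FALSE],
          axis = "columns", z_score = TRUE
        )
        risk <- cut_clusters(hc, k = 2) |> rename(aoi_id = "item")
        readr::write_tsv(risk, file.path(out, "risk_clusters.tsv"))
        writeLines(
          dendrogram_newick(hc),
          file.path(out, "risk_dendrogram.nwk")
        )
      }
    }
    manifest$stages$explore <- list(
      pca_components = nrow(pca$variance),
      risk_clusters = if (is.null(risk)) 0L else length(unique(risk$cluster))
    )
  }

  jsonlite::write_json(manifest, manifest_file,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
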