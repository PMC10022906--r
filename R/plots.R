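# ggplot2 views of the main result types

#' Volcano plot of a differential-expression fit
#'
#' @param object a `dsp_de` fit.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.dsp_de <- function(object, ...) {
  tab <- tidy(object) |>
    mutate(status = case_when(
      .data$significant & .data$log2fc > 0 ~ "up",
      .data$significant ~ "down",
      TRUE ~ "ns"
    ))
  ggplot(tab, aes(.data$log2fc, -log10(.data$p_adj), colour = .data$status)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_vline(xintercept = c(-object$lfc, object$lfc), linetype = 2) +
    geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", ns = "grey70")
    ) +
    labs(
      title = object$contrast, x = "log2 fold change",
      y = "-log10 adjusted P", colour = NULL
    ) +
    theme_bw()
}

#' Scatter of AOI principal-component scores
#'
#' @param object a `dsp_pca`.
#' @param annotation optional AOI annotation joined on `aoi_id`; when
#'   given, points are coloured by subtype and shaped by grade.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.dsp_pca <- function(object, annotation = NULL, ...) {
  sc <- object$scores
  vf <- object$variance$variance_fraction
  p <- if (!is.null(annotation)) {
    sc <- left_join(sc, annotation, by = "aoi_id")
    ggplot(sc, aes(.data$PC1, .data$PC2,
      colour = .data$subtype, shape = .data$grade
    ))
  } else {
    ggplot(sc, aes(.data$PC1, .data$PC2))
  }
  p + geom_point(size = 2) +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * vf[2])
    ) +
    theme_bw()
}

#' Cluster-size overview of a coexpression network
#'
#' @param object a clustered `dsp_network`.
#' @param ... unused.
#' @return A ggplot of Leiden cluster sizes, coloured by retention.
#' @export
autoplot.dsp_network <- function(object, ...) {
  if (!"cluster" %in% names(object$nodes)) {
    abort("run leiden_communities() before plotting the network")
  }
  nodes <- object$nodes
  if (!"retained" %in% names(nodes)) nodes$retained <- TRUE
  sizes <- nodes |>
    group_by(.data$cluster, .data$retained) |>
    summarise(n = n(), .groups = "drop") |>
    arrange(desc(.data$n))
  sizes$cluster <- factor(sizes$cluster, levels = sizes$cluster)
  ggplot(sizes, aes(.data$cluster, .data$n, fill = .data$retained)) +
    geom_col() +
    labs(x = "Leiden cluster", y = "genes", fill = "retained") +
    theme_bw()
}

#' QC scatter of snAUC against sequencing yield
#'
#' @param qc per-AOI QC tibble from [qc_aois()].
#' @param min_counts,min_snauc thresholds drawn as dashed lines.
#' @return A ggplot.
#' @export
plot_qc <- function(qc, min_counts = 100000, min_snauc = 0.65) {
  ggplot(qc, aes(.data$total_counts, .data$snauc, colour = .data$pass)) +
    geom_point(size = 2) +
    geom_vline(xintercept = min_counts, linetype = 2) +
    geom_hline(yintercept = min_snauc, linetype = 2) +
    ggplot2::scale_x_log10() +
    labs(x = "total counts", y = "snAUC", colour = "pass") +
    theme_bw()
}

#' NES barplot of enrichment results
#'
#' @param res a `dsp_gsea` tibble (optionally multiple analyses).
#' @param alpha significance threshold used for the fill.
#' @return A ggplot.
#' @export
plot_enrichment <- function(res, alpha = 0.05) {
  res <- res |>
    filter(!is.na(.data$nes)) |>
    arrange(.data$nes) |>
    mutate(
      set = factor(.data$set, levels = unique(.data$set)),
      significant = .data$p_adj < alpha
    )
  ggplot(res, aes(.data$nes, .data$set, fill = .data$significant)) +
    geom_col() +
    labs(x = "normalized enrichment score", y = NULL, fill = sprintf("P_adj < %g", alpha)) +
    theme_bw()
}
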