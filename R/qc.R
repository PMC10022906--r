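#' Signal-to-noise ROC AUC of one AOI
#'
#' The snAUC statistic is the area under the ROC curve that treats
#' gene-probe counts as positives and negative-probe counts as negatives
#' within a single AOI. It equals the Mann-Whitney U statistic divided by
#' the number of (gene, negative) probe pairs, with ties contributing 1/2.
#' An AOI whose gene probes are indistinguishable from background scores
#' 0.5; complete separation scores 1.
#'
#' @param gene_probe_counts counts of the gene-targeting probes.
#' @param negative_probe_counts counts of the negative-control probes.
#' @return AUC in \[0, 1\].
#' @examples
#' compute_snauc(c(5, 6, 7), c(1, 2, 3)) # 1
#' compute_snauc(c(2, 3), c(2, 1)) # 0.875
#' @export
compute_snauc <- function(gene_probe_counts, negative_probe_counts) {
  if (length(gene_probe_counts) == 0L) {
    abort("no gene-probe counts supplied")
  }
  if (length(negative_probe_counts) == 0L) {
    abort("no negative-probe counts supplied")
  }
  if (any(gene_probe_counts < 0) || any(negative_probe_counts < 0)) {
    abort("counts must be non-negative")
  }
  n_g <- length(gene_probe_counts)
  n_n <- length(negative_probe_counts)
  r <- rank(c(gene_probe_counts, negative_probe_counts))
  u <- sum(r[seq_len(n_g)]) - n_g * (n_g + 1) / 2
  u / (n_g * n_n)
}

#' Per-AOI limit of detection
#'
#' The LOD is the 90th percentile of that AOI's negative-probe counts,
#' computed with the linear-interpolation percentile convention
#' (`stats::quantile()` type 7). A probe count strictly below the LOD is
#' considered undetectable; see [is_detected()].
#'
#' @param negative_probe_counts counts of the negative-control probes in
#'   one AOI.
#' @param probability percentile used; default 0.9.
#' @return LOD as a length-1 numeric >= 0.
#' @export
compute_lod <- function(negative_probe_counts, probability = 0.9) {
  if (length(negative_probe_counts) == 0L) {
    abort("at least one negative-probe count is required to compute an LOD")
  }
  unname(quantile(negative_probe_counts, probability, type = 7))
}

#' Detection call against a limit of detection
#'
#' Counts strictly below the LOD are undetectable; a count equal to the
#' LOD is detected.
#'
#' @param count numeric count(s).
#' @param lod limit of detection.
#' @return Logical, vectorised over `count`.
#' @export
is_detected <- function(count, lod) count >= lod

#' Per-AOI LODs of a probe-count object
#'
#' Applies [compute_lod()] to each AOI's negative probes.
#'
#' @param pc a [probe_counts()] object.
#' @param probability percentile used; default 0.9.
#' @return Named numeric vector, one LOD per AOI.
#' @export
aoi_lods <- function(pc, probability = 0.9) {
  neg <- split_probes(pc)$negative
  apply(neg, 2, compute_lod, probability = probability)
}

#' Per-AOI quality-control metrics
#'
#' Computes, for every AOI: total counts, snAUC, LOD, the percentage of
#' gene probes detected at or above the LOD, and the pass/fail decision
#' with its reasons. An AOI passes when it has strictly more than
#' `min_counts` total aligned deduplicated counts and snAUC strictly above
#' `min_snauc`.
#'
#' @param pc a [probe_counts()] object.
#' @param min_counts total-count threshold (default 100000).
#' @param min_snauc snAUC threshold (default 0.65).
#' @return Tibble with one row per AOI: `aoi_id`, `total_counts`, `snauc`,
#'   `lod`, `pct_probes_detected`, `pass`, `reasons`.
#' @export
qc_aois <- function(pc, min_counts = 100000, min_snauc = 0.65) {
  sp <- split_probes(pc)
  total <- colSums(pc$counts)
  snauc <- vapply(
    seq_len(ncol(pc$counts)),
    function(j) compute_snauc(sp$gene[, j], sp$negative[, j]),
    numeric(1)
  )
  lod <- aoi_lods(pc)
  pct_det <- vapply(
    seq_len(ncol(pc$counts)),
    function(j) 100 * mean(is_detected(sp$gene[, j], lod[j])),
    numeric(1)
  )
  reasons <- purrr::map2_chr(unname(total), snauc, function(tt, aa) {
    r <- c(
      if (tt <= min_counts) "low counts",
      if (aa <= min_snauc) "low snAUC"
    )
    if (length(r) == 0) "" else paste(r, collapse = "; ")
  })
  tibble(
    aoi_id = colnames(pc$counts),
    total_counts = unname(total),
    snauc = snauc,
    lod = unname(lod),
    pct_probes_detected = pct_det,
    pass = total > min_counts & snauc > min_snauc,
    reasons = reasons
  )
}

#' Filter AOIs on sequencing yield and signal-to-noise
#'
#' Retains AOIs with strictly more than `min_counts` total counts and
#' snAUC strictly above `min_snauc`. Rows (probes) are untouched.
#'
#' @inheritParams qc_aois
#' @return List with `probe_counts` (the column-filtered object) and `qc`
#'   (the full per-AOI QC tibble, including removed AOIs with reasons).
#' @export
filter_aois <- function(pc, min_counts = 100000, min_snauc = 0.65) {
  qc <- qc_aois(pc, min_counts = min_counts, min_snauc = min_snauc)
  if (!any(qc$pass)) abort("no AOIs pass QC")
  kept <- qc$aoi_id[qc$pass]
  list(
    probe_counts = probe_counts(
      pc$counts[, kept, drop = FALSE],
      pc$manifest
    ),
    qc = qc
  )
}

#' Remove gene probes that are rarely detected
#'
#' A gene probe is removed when it is undetected (strictly below the
#' per-AOI LOD) in strictly more than `max_undetected_frac` of AOIs.
#' Negative-control probes are never removed.
#'
#' @param pc a [probe_counts()] object.
#' @param max_undetected_frac fraction threshold (default 0.80).
#' @return The row-filtered [probe_counts()] object.
#' @export
filter_probes <- function(pc, max_undetected_frac = 0.80) {
  lod <- aoi_lods(pc)
  undet_frac <- rowMeans(!is_detected(
    pc$counts, matrix(lod, nrow(pc$counts), ncol(pc$counts), byrow = TRUE)
  ))
  drop <- undet_frac > max_undetected_frac & !pc$manifest$is_negative
  probe_counts(pc$counts[!drop, , drop = FALSE], pc$manifest[!drop, ])
}

#' Collapse probes to one expression value per gene
#'
#' Per (gene, AOI), the collapsed value is the geometric mean of the gene's
#' surviving probe counts, with zeros replaced by 1 beforehand (see
#' [geo_mean()]). Genes left with no surviving probes are absent from the
#' output.
#'
#' @param pc a [probe_counts()] object (typically after [filter_probes()]).
#' @return Genes-by-AOIs matrix at stage `collapsed_raw`.
#' @export
collapse_probes <- function(pc) {
  sp <- split_probes(pc)
  if (nrow(sp$gene) == 0L) abort("no gene probes left to collapse")
  logs <- log(pmax(sp$gene, 1))
  genes <- sort(unique(sp$gene_map))
  idx <- split(seq_len(nrow(sp$gene)), sp$gene_map)[genes]
  collapsed <- t(vapply(
    idx,
    function(i) exp(colMeans(logs[i, , drop = FALSE])),
    numeric(ncol(sp$gene))
  ))
  dimnames(collapsed) <- list(genes, colnames(sp$gene))
  new_gene_expr(collapsed, "collapsed_raw")
}

#' Retain genes detected above background in enough AOIs
#'
#' A gene is retained when its collapsed value is at or above the AOI's
#' LOD in at least `min_detected_frac` of AOIs (inclusive).
#'
#' @param expr collapsed genes-by-AOIs matrix.
#' @param lods named per-AOI LOD vector (from the negative probes of the
#'   same AOIs); names must cover `colnames(expr)`.
#' @param min_detected_frac fraction threshold (default 0.20).
#' @return The row-filtered expression matrix, same stage.
#' @export
filter_genes <- function(expr, lods, min_detected_frac = 0.20) {
  assert_expr(expr)
  if (!all(colnames(expr) %in% names(lods))) {
    abort("LODs are missing for some AOIs in the expression matrix")
  }
  lod <- lods[colnames(expr)]
  det_frac <- rowMeans(is_detected(
    expr, matrix(lod, nrow(expr), ncol(expr), byrow = TRUE)
  ))
  keep <- det_frac >= min_detected_frac
  if (!any(keep)) abort("no genes pass the detection filter")
  new_gene_expr(expr[keep, , drop = FALSE], expr_stage(expr))
}
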