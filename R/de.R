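# Moderated two-group differential expression.
#
# Per gene, an ordinary least-squares two-group fit on log2 expression;
# residual variances are shrunk toward a common prior by the standard
# empirical-Bayes construction: gene variances are modelled as scaled
# inverse-chi-square draws, and the prior degrees of freedom and prior
# variance are estimated by moment matching of the log-variances
# (digamma/trigamma matching). The moderated t statistic then uses the
# posterior variance and gains the prior degrees of freedom.

# Newton solve of trigamma(y) = x (decreasing, convex on (0, Inf)).
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes squeezing of gene-level variances
#'
#' Estimates a scaled inverse-chi-square prior for gene residual variances
#' by moment matching on the log scale, and returns the posterior
#' (squeezed) variances \eqn{(d_0 s_0^2 + d s_g^2) / (d_0 + d)}.
#'
#' @param s2 gene-level sample variances.
#' @param df residual degrees of freedom of each `s2` (scalar).
#' @param prior_df optional prior degrees-of-freedom override. `0` disables
#'   shrinkage (ordinary t), `Inf` shrinks completely to the common value.
#' @return List: `var_post`, `var_prior`, `df_prior`.
#' @export
squeeze_var <- function(s2, df, prior_df = NULL) {
  stopifnot(length(df) == 1L, df > 0)
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) {
    # degenerate: no information about the variance distribution
    out <- list(var_post = pmax(s2, 1e-12), var_prior = NA_real_, df_prior = 0)
    if (!is.null(prior_df)) out$df_prior <- prior_df
    return(out)
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- if (sum(ok) > 1) var(e) - trigamma(df / 2) else -1
  if (is.null(prior_df)) {
    if (is.na(evar) || evar <= 0) {
      df_prior <- Inf
    } else {
      df_prior <- 2 * trigamma_inverse(evar)
    }
  } else {
    df_prior <- prior_df
  }
  if (is.infinite(df_prior)) {
    # no evidence of variance heterogeneity: shrink completely to the
    # common value (raw-scale mean, so equal variances are a no-op)
    var_prior <- mean(s2[ok])
    var_post <- rep(var_prior, length(s2))
  } else if (df_prior == 0) {
    var_prior <- exp(emean)
    var_post <- s2
  } else {
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    var_post <- (df_prior * var_prior + df * s2) / (df_prior + df)
  }
  list(var_post = var_post, var_prior = var_prior, df_prior = df_prior)
}

#' Define a two-group contrast over AOI annotations
#'
#' Groups are given as tidy filter expressions over the annotation table
#' (e.g. `subtype == "PB"`), or as character vectors of AOI ids.
#'
#' @param name contrast label; fold changes are log2(A) - log2(B).
#' @param a,b expressions selecting group A and group B rows of the
#'   annotation, or character vectors of `aoi_id`s.
#' @return A `dsp_contrast` object.
#' @examples
#' de_contrast("PBvsGF", subtype == "PB", subtype == "GF")
#' @export
de_contrast <- function(name, a, b) {
  structure(
    list(name = name, a = enquo(a), b = enquo(b)),
    class = "dsp_contrast"
  )
}

resolve_group <- function(q, annotation) {
  v <- eval_tidy(q, data = annotation)
  if (is.logical(v)) annotation$aoi_id[v & !is.na(v)] else as.character(v)
}

resolve_contrast <- function(contrast, annotation, aois = NULL) {
  ids_a <- resolve_group(contrast$a, annotation)
  ids_b <- resolve_group(contrast$b, annotation)
  if (!is.null(aois)) {
    ids_a <- intersect(ids_a, aois)
    ids_b <- intersect(ids_b, aois)
  }
  if (length(intersect(ids_a, ids_b))) {
    abort(sprintf("contrast '%s': groups overlap", contrast$name))
  }
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    abort(sprintf(
      "contrast '%s': both groups need >= 2 AOIs (got %d and %d)",
      contrast$name, length(ids_a), length(ids_b)
    ))
  }
  list(a = ids_a, b = ids_b)
}

#' Fit a moderated two-group contrast
#'
#' @param expr log2 genes-by-AOIs expression matrix.
#' @param annotation AOI annotation tibble with an `aoi_id` column.
#' @param contrast a [de_contrast()].
#' @param lfc,alpha thresholds used for the `significant` flag:
#'   `|log2fc| > lfc` and `p_adj < alpha` (defaults 1.0 and 0.05).
#' @param prior_df optional override of the estimated prior degrees of
#'   freedom; `0` reduces the fit to ordinary t-tests.
#' @return A `dsp_de` object; use [tidy()] for the per-gene table
#'   (`gene`, `log2fc`, `t`, `p_value`, `p_adj`, `significant`) and
#'   [glance()] for the fit summary.
#' @export
fit_contrast <- function(expr, annotation, contrast,
                         lfc = 1.0, alpha = 0.05, prior_df = NULL) {
  assert_expr(expr, "log")
  groups <- resolve_contrast(contrast, annotation, aois = colnames(expr))
  xa <- expr[, groups$a, drop = FALSE]
  xb <- expr[, groups$b, drop = FALSE]
  na <- ncol(xa)
  nb <- ncol(xb)
  df <- na + nb - 2
  d <- rowMeans(xa) - rowMeans(xb)
  ssa <- rowSums((xa - rowMeans(xa))^2)
  ssb <- rowSums((xb - rowMeans(xb))^2)
  s2 <- (ssa + ssb) / df
  sq <- squeeze_var(s2, df, prior_df = prior_df)
  se <- sqrt(pmax(sq$var_post, 1e-300) * (1 / na + 1 / nb))
  tstat <- d / se
  df_total <- df + sq$df_prior
  p <- 2 * pt(-abs(tstat), df = df_total)
  p_adj <- p.adjust(p, method = "BH")
  table <- tibble(
    gene = rownames(expr),
    log2fc = unname(d),
    t = unname(tstat),
    p_value = unname(p),
    p_adj = unname(p_adj),
    significant = abs(d) > lfc & p_adj < alpha
  )
  structure(
    list(
      table = table, contrast = contrast$name,
      n_a = na, n_b = nb,
      df_residual = df, df_prior = sq$df_prior, var_prior = sq$var_prior,
      lfc = lfc, alpha = alpha
    ),
    class = "dsp_de"
  )
}

#' @export
print.dsp_de <- function(x, ...) {
  cat(sprintf(
    "<dsp_de> %s: %d genes, n = %d vs %d, prior df = %.2f, %d significant (|log2FC| > %g & P_adj < %g)\n",
    x$contrast, nrow(x$table), x$n_a, x$n_b, x$df_prior,
    sum(x$table$significant), x$lfc, x$alpha
  ))
  invisible(x)
}

#' @export
tidy.dsp_de <- function(x, ...) x$table

#' @export
glance.dsp_de <- function(x, ...) {
  tibble(
    contrast = x$contrast, n_genes = nrow(x$table),
    n_a = x$n_a, n_b = x$n_b,
    df_prior = x$df_prior, var_prior = x$var_prior,
    n_significant = sum(x$table$significant)
  )
}

#' Benjamini-Hochberg adjustment with validation
#'
#' Step-up false discovery rate control via `stats::p.adjust`.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return Adjusted p-values in \[0, 1\], same length.
#' @export
adjust_bh <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' @param results a `dsp_de` object or its [tidy()] table.
#' @param lfc absolute log2 fold-change threshold (strict `>`; default 1).
#' @param alpha adjusted p-value threshold (strict `<`; default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
call_de <- function(results, lfc = 1.0, alpha = 0.05) {
  tab <- if (inherits(results, "dsp_de")) results$table else as_tibble(results)
  list(
    up = tab$gene[tab$log2fc > lfc & tab$p_adj < alpha],
    down = tab$gene[tab$log2fc < -lfc & tab$p_adj < alpha]
  )
}

#' Subtype-specific signatures from pairwise contrasts
#'
#' A gene is subtype-specific when it is upregulated in that subtype in
#' both of its pairwise comparisons: PB-specific genes are up in PB vs GF
#' and in PB vs INT; GF-specific up in GF vs PB and GF vs INT;
#' INT-specific up in INT vs PB and INT vs GF. The union of the three
#' signatures forms the histologic subtype signature.
#'
#' @param pb_gf,pb_int,int_gf `dsp_de` fits of the contrasts PB vs GF,
#'   PB vs INT and INT vs GF (in those orientations).
#' @param lfc,alpha DE thresholds passed to [call_de()].
#' @return List with per-subtype gene vectors (`PB`, `GF`, `INT`) and a
#'   `union` tibble (`gene`, `subtype`) recording provenance.
#' @export
build_subtype_signatures <- function(pb_gf, pb_int, int_gf,
                                     lfc = 1.0, alpha = 0.05) {
  for (fit in list(pb_gf, pb_int, int_gf)) {
    if (!inherits(fit, "dsp_de")) abort("all three contrasts are required as dsp_de fits")
  }
  c_pb_gf <- call_de(pb_gf, lfc, alpha)
  c_pb_int <- call_de(pb_int, lfc, alpha)
  c_int_gf <- call_de(int_gf, lfc, alpha)
  sigs <- list(
    PB = intersect(c_pb_gf$up, c_pb_int$up),
    GF = intersect(c_pb_gf$down, c_int_gf$down),
    INT = intersect(c_pb_int$down, c_int_gf$up)
  )
  union_tbl <- bind_rows(lapply(names(sigs), function(s) {
    if (length(sigs[[s]]) == 0) return(NULL)
    tibble(gene = sigs[[s]], subtype = s)
  }))
  if (is.null(union_tbl) || ncol(union_tbl) == 0) {
    union_tbl <- tibble(gene = character(), subtype = character())
  }
  c(sigs, list(union = arrange(union_tbl, .data$gene)))
}

#' Curate gene sets from an external differential-expression table
#'
#' External tables (e.g. tumour-vs-normal RNA-seq results) are converted to
#' up/down gene sets using inclusive fold-change thresholds
#' (`|log2fc| >= lfc`) and `p_adj < alpha`; duplicate symbols are merged.
#'
#' @param de_table data frame with columns `gene`, `log2fc`, `p_adj`.
#' @param lfc inclusive absolute log2 fold-change threshold (default 1.0).
#' @param alpha adjusted p-value threshold (default 0.05).
#' @param name base name for the emitted sets.
#' @return Named list of two character vectors, `<name>_up` and
#'   `<name>_down`, ready for [write_gmt()].
#' @export
build_external_gene_sets <- function(de_table, lfc = 1.0, alpha = 0.05,
                                     name = "external") {
  de_table <- as_tibble(de_table)
  required <- c("gene", "log2fc", "p_adj")
  if (!all(required %in% names(de_table))) {
    abort(paste0("de_table must have columns: ", paste(required, collapse = ", ")))
  }
  up <- unique(de_table$gene[de_table$log2fc >= lfc & de_table$p_adj < alpha])
  down <- unique(de_table$gene[de_table$log2fc <= -lfc & de_table$p_adj < alpha])
  setNames(list(up, down), paste0(name, c("_up", "_down")))
}
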