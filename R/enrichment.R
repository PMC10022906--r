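# Preranked gene-set enrichment.
#
# ES is the maximum deviation of the weighted Kolmogorov-Smirnov running
# sum over the ranked list: hits increment proportionally to |statistic|
# (weight exponent 1), misses decrement uniformly. The null distribution
# comes from random same-size gene subsets of the ranked universe; NES is
# ES divided by the mean |null ES| of matching sign, and the p-value is
# the fraction of same-sign null ES at least as extreme.

# running-sum ES for a hit indicator over stats sorted in decreasing order
gsea_es <- function(stat_sorted, hit) {
  n <- length(stat_sorted)
  nh <- sum(hit)
  nr <- sum(abs(stat_sorted[hit]))
  inc <- numeric(n)
  if (nr > 0) {
    inc[hit] <- abs(stat_sorted[hit]) / nr
  } else {
    inc[hit] <- 1 / nh # all-zero statistics: uniform hit weight
  }
  if (nh < n) inc[!hit] <- -1 / (n - nh)
  run <- cumsum(inc)
  i <- which.max(abs(run))
  list(es = run[i], peak = i, run = run)
}

#' Preranked gene-set enrichment analysis
#'
#' @param ranked data frame with columns `gene` and `stat` (typically the
#'   log2 fold change of a DE analysis), or a named numeric vector.
#'   Genes are ranked by decreasing `stat`.
#' @param sets named list of gene-symbol vectors (see [read_gmt()]). Genes
#'   absent from the ranked universe are dropped before testing.
#' @param n_perm number of random same-size gene subsets drawn for the
#'   null (>= 100).
#' @param min_size,max_size post-intersection set-size bounds; sets
#'   outside the bounds are skipped with a warning.
#' @param seed seed for the permutation null.
#' @param exhaustive if `TRUE` and `choose(universe, set size)` is at most
#'   `exhaustive_limit`, enumerate every same-size subset instead of
#'   sampling, making ES null and p-value exact.
#' @param exhaustive_limit maximum number of subsets to enumerate.
#' @return Tibble of class `dsp_gsea`: `set`, `size`, `es`, `nes`,
#'   `p_value`, `p_adj`, `leading_edge` (list-column).
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, min_size = 5,
                           max_size = 500, seed = 1L, exhaustive = FALSE,
                           exhaustive_limit = 1e5) {
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked <- tibble(gene = names(ranked), stat = unname(ranked))
  }
  ranked <- as_tibble(ranked)
  if (!all(c("gene", "stat") %in% names(ranked))) {
    abort("`ranked` must have columns gene and stat")
  }
  if (nrow(ranked) == 0) abort("ranked list is empty")
  if (anyNA(ranked$stat)) abort("ranked statistics must not be missing")
  if (anyDuplicated(ranked$gene)) abort("ranked gene symbols must be unique")
  if (n_perm < 100) abort("n_perm must be at least 100")
  ord <- order(ranked$stat, decreasing = TRUE)
  genes <- ranked$gene[ord]
  stats_sorted <- ranked$stat[ord]
  n <- length(genes)

  sizes <- vapply(sets, function(s) length(intersect(s, genes)), integer(1))
  skip <- sizes < min_size | sizes > max_size | sizes >= n
  if (any(skip)) {
    warn(paste0(
      "skipping ", sum(skip), " gene set(s) outside size bounds after ",
      "intersection with the universe: ",
      paste(head(names(sets)[skip], 5), collapse = ", "),
      if (sum(skip) > 5) ", ..." else ""
    ))
  }
  sets <- sets[!skip]
  sizes <- sizes[!skip]
  if (length(sets) == 0) {
    out <- tibble(
      set = character(), size = integer(), es = numeric(), nes = numeric(),
      p_value = numeric(), p_adj = numeric(), leading_edge = list()
    )
    class(out) <- c("dsp_gsea", class(out))
    return(out)
  }

  # one null ensemble per distinct set size
  set.seed(derive_seed(seed, "gsea"))
  null_for_size <- function(k) {
    if (exhaustive && choose(n, k) <= exhaustive_limit) {
      combos <- combn(n, k)
      vapply(seq_len(ncol(combos)), function(j) {
        hit <- logical(n)
        hit[combos[, j]] <- TRUE
        gsea_es(stats_sorted, hit)$es
      }, numeric(1))
    } else {
      vapply(seq_len(n_perm), function(b) {
        hit <- logical(n)
        hit[sample.int(n, k)] <- TRUE
        gsea_es(stats_sorted, hit)$es
      }, numeric(1))
    }
  }
  nulls <- lapply(unique(sizes), null_for_size)
  names(nulls) <- as.character(unique(sizes))

  rows <- purrr::map2(names(sets), sizes, function(nm, k) {
    hit <- genes %in% sets[[nm]]
    res <- gsea_es(stats_sorted, hit)
    null_es <- nulls[[as.character(k)]]
    same <- if (res$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    denom <- mean(abs(same))
    nes <- if (length(same) && denom > 0) res$es / denom else NA_real_
    if (exhaustive && choose(n, k) <= exhaustive_limit) {
      # tolerance guards exact ties recomputed in different float order
      p <- if (length(same)) mean(abs(same) >= abs(res$es) - 1e-9) else 1
    } else {
      p <- if (length(same)) {
        (1 + sum(abs(same) >= abs(res$es) - 1e-9)) / (1 + length(same))
      } else {
        1
      }
    }
    le <- if (res$es >= 0) {
      genes[seq_len(res$peak)][hit[seq_len(res$peak)]]
    } else {
      genes[res$peak:n][hit[res$peak:n]]
    }
    tibble(
      set = nm, size = k, es = res$es, nes = nes, p_value = p,
      leading_edge = list(le)
    )
  })
  out <- bind_rows(rows)
  out$p_adj <- adjust_bh(out$p_value)
  out <- out[, c("set", "size", "es", "nes", "p_value", "p_adj", "leading_edge")]
  class(out) <- c("dsp_gsea", class(out))
  out
}

#' Hypergeometric over-representation test for gene clusters
#'
#' Upper-tail hypergeometric probability \eqn{P(X \ge k)} of observing `k`
#' or more members of an annotation set when `|cluster|` genes are drawn
#' from the universe, with BH adjustment across annotation sets.
#'
#' @param cluster character vector of genes (must lie in `universe`).
#' @param annotation_sets named list of gene sets; membership is taken
#'   after intersection with the universe.
#' @param universe character vector, the tested gene universe.
#' @return Tibble: `set`, `set_size`, `overlap`, `p_value`, `p_adj`.
#' @examples
#' hypergeometric_enrich(
#'   cluster = c("a", "b", "c", "d"),
#'   annotation_sets = list(s = c("a", "b", "c", "d", "e")),
#'   universe = letters[1:10]
#' ) # p = 5/210
#' @export
hypergeometric_enrich <- function(cluster, annotation_sets, universe) {
  if (length(universe) == 0) abort("universe is empty")
  universe <- unique(universe)
  cluster <- unique(cluster)
  if (!all(cluster %in% universe)) {
    abort("cluster contains genes outside the universe")
  }
  n_u <- length(universe)
  n_c <- length(cluster)
  rows <- purrr::imap(annotation_sets, function(s, nm) {
    s <- intersect(s, universe)
    k <- length(intersect(cluster, s))
    p <- if (n_c == 0) 1 else phyper(k - 1, length(s), n_u - length(s), n_c,
      lower.tail = FALSE
    )
    tibble(set = nm, set_size = length(s), overlap = k, p_value = p)
  })
  out <- bind_rows(rows)
  out$p_adj <- adjust_bh(out$p_value)
  out
}
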