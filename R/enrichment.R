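#' One-sided Fisher overlap test
#'
#' Hypergeometric upper-tail probability of observing at least the seen
#' overlap between a query gene list and a gene set within a universe —
#' the one-sided Fisher's exact test for enrichment.
#'
#' @param query character vector of query gene ids (subset of `universe`).
#' @param gene_set character vector of set member ids (subset of
#'   `universe`).
#' @param universe character vector of all eligible gene ids.
#' @return a list with `overlap`, `p`, and the 2x2 `table`.
#' @export
fisher_overlap <- function(query, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(intersect(query, universe))
  gene_set <- unique(intersect(gene_set, universe))
  k <- length(intersect(query, gene_set))
  m <- length(gene_set)
  n <- length(universe) - m
  p <- stats::phyper(k - 1, m, n, length(query), lower.tail = FALSE)
  tab <- matrix(c(k, length(query) - k, m - k, n - (length(query) - k)),
                2, 2, dimnames = list(c("in_query", "out_query"),
                                      c("in_set", "out_set")))
  list(overlap = k, p = p, table = tab)
}

#' Fisher enrichment of a gene list across a collection, with local fdr
#'
#' Runs [fisher_overlap()] for every set of a collection and controls the
#' results with [tail_fdr()] (local and tail-based false discovery rates
#' over the collection's p-values). Significance conventions of the
#' analysis: `lfdr < 0.05` for broad (GO-slim-like) collections, stricter
#' cutoffs for large collections of small terms.
#'
#' @param query character vector of query gene ids.
#' @param gene_sets named list of member-id vectors.
#' @param universe character vector of all eligible gene ids.
#' @param lfdr_threshold significance cutoff on the local fdr.
#' @return data frame per set: `set`, `set_size`, `overlap`, `p`, `q`,
#'   `lfdr`, `significant`.
#' @export
fisher_enrichment <- function(query, gene_sets, universe,
                              lfdr_threshold = 0.05) {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  if (any(lengths(gene_sets) == 0)) stop("empty gene set(s) in collection")
  res <- lapply(gene_sets, fisher_overlap, query = query,
                universe = universe)
  p <- vapply(res, `[[`, numeric(1), "p")
  fd <- suppressWarnings(tail_fdr(p))
  data.frame(set = names(gene_sets),
             set_size = vapply(gene_sets, function(s)
               length(intersect(s, universe)), integer(1)),
             overlap = vapply(res, `[[`, numeric(1), "overlap"),
             p = p, q = fd$q, lfdr = fd$lfdr,
             significant = !is.na(fd$lfdr) & fd$lfdr < lfdr_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Signed significance ranking statistic
#'
#' `-sign(slope) * log10(p)` per gene: strongly significant positive growth
#' dependence ranks at the top, strongly significant negative dependence at
#' the bottom, so a ranked gene-set enrichment over this statistic probes
#' sector structure without any significance cutoff. Zero p-values are
#' substituted by the smallest value preserving the order (one decade
#' beyond the most extreme finite statistic); affected genes are recorded.
#'
#' @param fits a `"growth_law_fits"` table (or any data frame with
#'   `gene_id`, `slope`, `p_value`).
#' @return named numeric vector of ranking values; genes with substituted
#'   p = 0 are listed in the `"p_zero"` attribute.
#' @export
rank_statistic <- function(fits) {
  p <- fits$p_value; a <- fits$slope
  val <- -sign(a) * log10(p)
  zero <- !is.na(p) & p == 0 & !is.na(a) & a != 0
  if (any(zero)) {
    cap <- max(abs(val[is.finite(val)]), 0) + 1
    val[zero] <- cap * -sign(a[zero]) * -1   # -sign(a) * log10(0+) -> sign(a)*Inf
  }
  val[!is.na(a) & a == 0] <- 0
  stats::setNames(val, fits$gene_id)
}

#' Preranked gene-set enrichment analysis
#'
#' Classical preranked GSEA: genes are ordered by decreasing ranking value
#' and a weighted Kolmogorov-Smirnov running sum (weight
#' `|value|^weight_exponent` inside the set, uniform decrement outside)
#' gives the enrichment score ES (the extremum of the running sum). The
#' null is generated by gene-label permutation; NES divides ES by the mean
#' |null ES| of the same sign, and the permutation p-values are BH-adjusted
#' across sets. Leading-edge genes are the set members at or before the
#' running-sum extremum.
#'
#' @param stats named numeric vector of finite ranking values (one per
#'   gene).
#' @param gene_sets named list of member-id vectors.
#' @param n_perm number of label permutations (warns below 100).
#' @param weight_exponent 1 for classic weighted GSEA, 0 for the
#'   unweighted KS statistic.
#' @param min_size,max_size set-size bounds after restriction to the
#'   ranked genes.
#' @param seed optional integer seed.
#' @return data frame per retained set: `set`, `size`, `es`, `nes`, `p`,
#'   `p_adj`, `leading_edge` (comma-joined ids).
#' @export
preranked_gsea <- function(stats, gene_sets, n_perm = 1000,
                           weight_exponent = 1, min_size = 5,
                           max_size = 500, seed = NULL) {
  stopifnot(is.numeric(stats), !is.null(names(stats)))
  if (any(!is.finite(stats))) stop("ranking values must be finite")
  if (n_perm < 100) warning("fewer than 100 permutations: p-values coarse")
  if (!is.null(seed)) set.seed(seed)
  ord <- order(stats, decreasing = TRUE)
  sorted <- stats[ord]
  genes <- names(sorted)
  sets <- lapply(gene_sets, function(s) which(genes %in% s))
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  sets <- sets[keep]
  if (length(sets) == 0L) stop("no gene set within the size bounds")
  w <- abs(sorted)^weight_exponent
  obs <- lapply(sets, function(idx) gsea_es(idx, w))
  null_es <- matrix(NA_real_, n_perm, length(sets))
  n <- length(genes)
  for (b in seq_len(n_perm)) {
    for (j in seq_along(sets)) {
      idx <- sample.int(n, length(sets[[j]]))
      null_es[b, j] <- gsea_es(idx, w)$es
    }
  }
  es <- vapply(obs, `[[`, numeric(1), "es")
  nes <- p <- numeric(length(sets))
  for (j in seq_along(sets)) {
    same <- null_es[, j][sign(null_es[, j]) == sign(es[j])]
    nes[j] <- if (length(same)) es[j] / mean(abs(same)) else NA_real_
    p[j] <- (1 + sum(abs(same) >= abs(es[j]))) / (1 + length(same))
  }
  le <- vapply(seq_along(sets), function(j) {
    idx <- sets[[j]]; peak <- obs[[j]]$peak
    members <- if (es[j] >= 0) idx[idx <= peak] else idx[idx >= peak]
    paste(genes[members], collapse = ",")
  }, character(1))
  data.frame(set = names(sets), size = lengths(sets), es = es, nes = nes,
             p = p, p_adj = stats::p.adjust(p, method = "BH"),
             leading_edge = le, stringsAsFactors = FALSE, row.names = NULL)
}

## Weighted KS running sum over a sorted ranking; idx = positions of set
## members in the sorted order. Returns the signed extremum and its
## position.
gsea_es <- function(idx, w) {
  n <- length(w)
  inc <- numeric(n)
  tot <- sum(w[idx])
  if (tot == 0) {            # all member weights zero: fall back to counts
    inc[idx] <- 1 / length(idx)
  } else {
    inc[idx] <- w[idx] / tot
  }
  dec <- 1 / (n - length(idx))
  run <- cumsum(inc - ifelse(seq_len(n) %in% idx, 0, dec))
  peak <- which.max(abs(run))
  list(es = run[peak], peak = peak, running = run)
}
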