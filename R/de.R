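#' Screen genes for between-condition variability
#'
#' One-way ANOVA per gene with conditions as groups, followed by Holm
#' step-down adjustment across genes. A gene is flagged as variable when
#' its adjusted p-value is below `alpha`, i.e. it varies more across
#' conditions than among biological replicates. The F statistics are
#' computed by vectorised sums of squares (identical to `aov` per gene).
#'
#' @param mat expression matrix, genes x samples (complete rows are used
#'   per gene; NAs excluded pairwise).
#' @param design sample design (`sample_id`, `condition`).
#' @param alpha familywise significance level.
#' @return data frame per gene: `gene_id`, `f`, `p`, `p_holm`, `variable`.
#' @export
anova_variability_screen <- function(mat, design, alpha = 0.05) {
  mat <- as.matrix(mat)
  idx <- match(design$sample_id, colnames(mat))
  if (anyNA(idx)) stop("design samples missing from the matrix")
  mat <- mat[, idx, drop = FALSE]
  g <- factor(design$condition)
  if (nlevels(g) < 2) stop("need at least 2 conditions")
  counts <- table(g)
  if (any(counts < 2)) stop("every condition needs at least 2 replicates")
  n <- ncol(mat); k <- nlevels(g)
  gm <- rowMeans(mat)
  group_means <- vapply(levels(g), function(l)
    rowMeans(mat[, g == l, drop = FALSE]), numeric(nrow(mat)))
  ssb <- as.numeric(group_means^2 %*% as.numeric(counts)) - n * gm^2
  sst <- rowSums(mat^2) - n * gm^2
  ssw <- sst - ssb
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  degenerate <- ssw <= 0 & ssb <= 0    # constant gene: F undefined, null
  p[degenerate] <- NA_real_
  p[ssw <= 0 & ssb > 0] <- 0
  p_holm <- stats::p.adjust(p, method = "holm")
  data.frame(gene_id = rownames(mat), f = f, p = p, p_holm = p_holm,
             variable = !is.na(p_holm) & p_holm < alpha,
             stringsAsFactors = FALSE)
}

#' Per-gene, per-sample growth normalization factors
#'
#' Converts fitted growth laws into the normalization machinery that
#' removes each gene's growth-rate trend before differential expression:
#' the fitted line gives predicted normalised counts
#' `p = slope * mu + intercept`, predicted raw counts `q = p * S` (with
#' size factors `S`), and normalization factors `N = n / p` (observed over
#' predicted normalised counts), rescaled per gene to geometric mean 1.
#' Genes with any non-positive prediction, genes without a fit, and
#' all-zero genes are excluded and reported. Zero observed counts would
#' give zero factors, which the downstream NB model cannot accept; they
#' are replaced by a half-count pseudo-observation before the ratio.
#'
#' @param counts raw count matrix, genes x samples.
#' @param design sample design (`sample_id`, `condition`, `replicate`,
#'   `mu`).
#' @param fits `"growth_law_fits"` for (at least) the matrix genes, fitted
#'   on the matching normalised counts.
#' @param sf per-sample size factors (default: recomputed from `counts`).
#' @return a list of class `"growth_normalization"`: `gene_id` (kept
#'   genes), `predicted_norm`, `predicted_raw`, `norm_factors` (all genes x
#'   samples), `size_factors`, `design`, `excluded` (list:
#'   `negative_prediction`, `all_zero`, `unfit`).
#' @export
growth_normalization_factors <- function(counts, design, fits,
                                         sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  idx <- match(design$sample_id, colnames(counts))
  if (anyNA(idx)) stop("design samples missing from the count matrix")
  counts <- counts[, idx, drop = FALSE]
  sf <- sf[idx]
  all_zero <- rownames(counts)[rowSums(counts) == 0]
  fi <- match(rownames(counts), fits$gene_id)
  unfit <- rownames(counts)[is.na(fi) | is.na(fits$slope[fi])]
  pred <- outer(seq_len(nrow(counts)), design$mu, function(g, mu)
    fits$slope[fi[g]] * mu + fits$intercept[fi[g]])
  dimnames(pred) <- dimnames(counts)
  neg_flag <- apply(pred, 1, function(r) any(!is.na(r) & r <= 0))
  neg <- setdiff(rownames(counts)[neg_flag], c(unfit, all_zero))
  keep <- setdiff(rownames(counts), c(all_zero, unfit, neg))
  pred <- pred[keep, , drop = FALSE]
  n <- sweep(counts[keep, , drop = FALSE], 2, sf, `/`)
  n_pos <- pmax(n, sweep(matrix(0.5, nrow(n), ncol(n)), 2, sf, `/`))
  nf <- n_pos / pred
  nf <- nf / exp(rowMeans(log(nf)))     # per-gene geometric mean 1
  structure(list(gene_id = keep, predicted_norm = pred,
                 predicted_raw = sweep(pred, 2, sf, `*`),
                 norm_factors = nf, size_factors = sf, design = design,
                 excluded = list(negative_prediction = neg,
                                 all_zero = all_zero, unfit = unfit)),
            class = "growth_normalization")
}

#' @export
print.growth_normalization <- function(x, ...) {
  cat("Growth normalization:", length(x$gene_id), "genes kept;",
      length(x$excluded$negative_prediction), "negative-prediction,",
      length(x$excluded$all_zero), "all-zero,",
      length(x$excluded$unfit), "unfit genes excluded\n")
  invisible(x)
}

#' Synthetic reference condition from predicted counts
#'
#' Builds a trend-free reference pseudo-condition: for each gene and
#' replicate, the reference count is the median over conditions of the
#' RMLM-predicted raw counts, rounded to the nearest integer.
#'
#' @param gn a `"growth_normalization"` object.
#' @return integer matrix, genes x replicates (columns `reference_r<k>`).
#' @export
synthetic_reference <- function(gn) {
  stopifnot(inherits(gn, "growth_normalization"))
  reps <- sort(unique(gn$design$replicate))
  s <- vapply(reps, function(k) {
    cols <- gn$design$replicate == k
    round(apply(gn$predicted_raw[, cols, drop = FALSE], 1, stats::median))
  }, numeric(length(gn$gene_id)))
  colnames(s) <- paste0("reference_r", reps)
  rownames(s) <- gn$gene_id
  storage.mode(s) <- "integer"
  s
}

#' Growth-rate-removed differential expression test
#'
#' Negative-binomial Wald test of each condition against the synthetic
#' reference, with per-gene, per-sample normalization that absorbs the
#' growth-rate trend. The counts analysed are the original raw counts of
#' the kept genes plus the reference columns; the normalization bias is
#' the RMLM-predicted raw count of each gene in each sample (the unrounded
#' reference medians for the reference columns), rescaled per gene to
#' geometric mean 1 and combined with median-of-ratios size factors.
#' Dividing observed by predicted counts in this way makes the reported
#' fold change the ratio of observed normalised counts to the counts
#' predicted by the gene's growth law, so a gene following its growth law
#' exactly has log2 fold change 0 in every condition and only
#' nutrient-specific residual expression is tested.
#'
#' The default engine is a compact NB analogue of the standard count-data
#' test: per-group means are ratio estimators on the normalised scale,
#' gene-wise dispersions come from method-of-moments across the real
#' condition groups and are shrunk towards a fitted mean-dispersion trend,
#' and the Wald variance of a contrast charges only the condition side —
#' the reference columns are a deterministic construction (medians of
#' model predictions), so they carry no sampling variance. With
#' `engine = "deseq2"` the test is instead delegated to DESeq2 with the
#' same normalization factors and the reference treated as an ordinary
#' group (a more conservative variance treatment); exact agreement between
#' the engines is not expected. BH adjustment is applied within each
#' contrast; there is no independent filtering or outlier replacement.
#'
#' @param counts raw count matrix, genes x samples.
#' @param design sample design.
#' @param fits optional precomputed `"growth_law_fits"` (default: fitted on
#'   the normalised counts).
#' @param gn optional precomputed `"growth_normalization"`.
#' @param shrink add shrunk fold changes via [shrink_lfc()].
#' @param engine `"internal"` (default) or `"deseq2"`.
#' @param prior_df strength of the dispersion-trend shrinkage, in degrees
#'   of freedom (internal engine).
#' @param quiet suppress DESeq2 progress messages (deseq2 engine).
#' @return a data frame of class `"de_table"`: `gene_id`, `condition`,
#'   `base_mean`, `log2fc_raw`, `lfc_se`, `p`, `p_adj` (and `log2fc_shrunk`
#'   when `shrink = TRUE`); the `"growth_normalization"` and reference
#'   matrix are attached as attributes.
#' @export
nb_de_test <- function(counts, design, fits = NULL, gn = NULL,
                       shrink = TRUE, engine = c("internal", "deseq2"),
                       prior_df = 8, quiet = TRUE) {
  engine <- match.arg(engine)
  counts <- as.matrix(counts)
  sf <- size_factors(counts)
  if (is.null(gn)) {
    if (is.null(fits))
      fits <- fit_growth_laws(normalize_counts(counts, sf), design)
    gn <- growth_normalization_factors(counts, design, fits, sf)
  }
  s <- synthetic_reference(gn)
  aug <- cbind(counts[gn$gene_id, gn$design$sample_id, drop = FALSE], s)
  condition <- factor(c(gn$design$condition,
                        rep("reference", ncol(s))),
                      levels = c("reference", unique(gn$design$condition)))
  ## normalization bias = predicted raw counts (trend); reference columns
  ## are already trend-free, their bias is the unrounded reference median
  reps <- sort(unique(gn$design$replicate))
  ref_bias <- vapply(reps, function(k)
    apply(gn$predicted_raw[, gn$design$replicate == k, drop = FALSE], 1,
          stats::median), numeric(length(gn$gene_id)))
  bias <- cbind(gn$predicted_raw, ref_bias)
  bias <- bias / exp(rowMeans(log(bias)))   # per-gene geometric mean 1
  out <- if (engine == "internal") {
    ## RMLM prediction uncertainty, propagated into the contrasts: the
    ## slope error of the fitted line shifts predictions by eps_a * mu,
    ## and the reference sits at the median growth rate, so a contrast
    ## carries var ~ var(eps_a) * (mu_j - mu_med)^2. The residual scale
    ## is MAD-based so condition effects do not inflate it.
    nmat <- sweep(counts[gn$gene_id, gn$design$sample_id, drop = FALSE],
                  2, gn$size_factors, `/`)
    resid_var <- apply(nmat - gn$predicted_norm, 1, function(r)
      (1.4826 * stats::median(abs(r)))^2)
    mu <- gn$design$mu
    ssq <- sum((mu - mean(mu))^2)
    fit_info <- list(resid_var = resid_var, mu = mu,
                     mu_med = stats::median(mu), ssq = ssq,
                     pred = gn$predicted_norm,
                     condition_of = gn$design$condition)
    nb_wald_internal(aug, bias, condition, prior_df = prior_df,
                     fit_info = fit_info)
  } else {
    nb_wald_deseq2(aug, bias, condition, quiet = quiet)
  }
  zero <- out$base_mean == 0
  out$log2fc_raw[zero] <- 0
  out$p[zero] <- 1; out$p_adj[zero] <- 1
  class(out) <- c("de_table", "data.frame")
  if (shrink) out <- shrink_lfc(out)
  attr(out, "growth_normalization") <- gn
  attr(out, "reference") <- s
  out
}

## Simplified NB Wald machinery: ratio-estimator group means on the
## normalised scale, pooled method-of-moments dispersions over the real
## groups shrunk to a 1/mean trend, and contrast variance from the
## condition side only (the reference is constructed, not sampled).
nb_wald_internal <- function(aug, bias, condition, prior_df = 8,
                             fit_info = NULL) {
  sf_aug <- DESeq2::estimateSizeFactorsForMatrix(aug / bias)
  nf <- sweep(bias, 2, sf_aug, `*`)
  z <- aug / nf
  groups <- levels(condition)
  ng <- nrow(aug)
  m_hat <- v_pois <- s2 <- matrix(NA_real_, ng, length(groups),
                                  dimnames = list(rownames(aug), groups))
  inv_nf_mean <- numeric(length(groups))
  n_rep <- integer(length(groups))
  for (j in seq_along(groups)) {
    cols <- condition == groups[j]
    n_rep[j] <- sum(cols)
    m_hat[, j] <- rowSums(aug[, cols, drop = FALSE]) /
      rowSums(nf[, cols, drop = FALSE])
    s2[, j] <- apply(z[, cols, drop = FALSE], 1, stats::var)
    ## Poisson component of var(z): mean of m / nf over the group
    v_pois[, j] <- m_hat[, j] * rowMeans(1 / nf[, cols, drop = FALSE])
  }
  real <- groups != "reference"
  ## gene-wise MoM dispersion pooled over real groups
  w <- n_rep[real] - 1L
  num <- sweep(s2[, real, drop = FALSE] - v_pois[, real, drop = FALSE],
               2, w, `*`)
  den <- sweep(m_hat[, real, drop = FALSE]^2, 2, w, `*`)
  disp_gene <- pmax(rowSums(num) / pmax(rowSums(den), 1e-12), 1e-8)
  ## mean-dispersion trend a/m + b fitted on moderately expressed genes
  base_mean <- rowMeans(m_hat[, real, drop = FALSE])
  ok <- base_mean > 1 & is.finite(disp_gene)
  trend <- if (sum(ok) >= 10) {
    cf <- stats::coef(stats::lm(disp_gene[ok] ~ I(1 / base_mean[ok])))
    pmax(cf[1], 0) + pmax(cf[2], 0) / base_mean
  } else rep(stats::median(disp_gene[ok], na.rm = TRUE), ng)
  ## the 1/mean regression is ill-conditioned when expression levels are
  ## homogeneous; keep the trend inside the observed dispersion range
  qs <- stats::quantile(disp_gene[ok], c(0.05, 0.95), na.rm = TRUE)
  trend <- pmin(pmax(trend, qs[1]), qs[2])
  gene_df <- sum(w)
  disp <- (gene_df * disp_gene + prior_df * pmax(trend, 1e-8)) /
    (gene_df + prior_df)
  ## dispersion outliers far above the trend are kept unshrunk, so a
  ## genuinely noisy gene is not handed an optimistic variance
  lres <- log(disp_gene) - log(pmax(trend, 1e-8))
  spread <- stats::mad(lres[is.finite(lres) & ok])
  outlier <- is.finite(lres) & lres > 2 * pmax(spread, 0.1)
  disp[outlier] <- disp_gene[outlier]
  ## Wald contrasts vs the reference; its columns are constructed from
  ## model predictions, so only the condition side carries variance
  var_log <- matrix(NA_real_, ng, length(groups))
  for (j in seq_along(groups)) {
    cols <- condition == groups[j]
    nf_j <- nf[, cols, drop = FALSE]
    var_mean <- (m_hat[, j] * rowSums(nf_j) +
                   disp * m_hat[, j]^2 * rowSums(nf_j^2)) /
      rowSums(nf_j)^2
    var_log[, j] <- var_mean / pmax(m_hat[, j], 1e-12)^2
  }
  ## add the propagated line-fit uncertainty (slope-error leverage, with
  ## a factor 2 for the efficiency of the repeated-median slope)
  if (!is.null(fit_info)) {
    for (j in which(real)) {
      cols <- fit_info$condition_of == groups[j]
      mu_j <- mean(fit_info$mu[cols])
      pred_j <- rowMeans(fit_info$pred[, cols, drop = FALSE])
      var_fit <- 2 * fit_info$resid_var * (mu_j - fit_info$mu_med)^2 /
        fit_info$ssq / pmax(pred_j, 1e-12)^2
      var_log[, j] <- var_log[, j] + var_fit
    }
  }
  ref <- which(groups == "reference")
  floor_m <- 0.5 / rowSums(nf[, condition == "reference", drop = FALSE])
  m_ref <- pmax(m_hat[, ref], floor_m)
  tabs <- lapply(groups[real], function(cn) {
    j <- which(groups == cn)
    m_j <- pmax(m_hat[, j], 0.5 / rowSums(nf[, condition == cn,
                                             drop = FALSE]))
    lfc <- log2(m_j / m_ref)
    se <- sqrt(var_log[, j]) / log(2)
    zstat <- lfc / se
    p <- 2 * stats::pnorm(-abs(zstat))
    data.frame(gene_id = rownames(aug), condition = cn,
               base_mean = base_mean, log2fc_raw = lfc, lfc_se = se,
               p = p, p_adj = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, tabs)
}

## DESeq2 route: same counts and normalization factors, reference treated
## as an ordinary group.
nb_wald_deseq2 <- function(aug, bias, condition, quiet = TRUE) {
  dds <- DESeq2::DESeqDataSetFromMatrix(aug,
                                        data.frame(condition = condition),
                                        ~condition)
  dds <- DESeq2::estimateSizeFactors(dds, normMatrix = bias)
  dds <- tryCatch(
    DESeq2::DESeq(dds, test = "Wald", fitType = "parametric", quiet = quiet),
    error = function(e) tryCatch(
      DESeq2::DESeq(dds, test = "Wald", fitType = "local", quiet = quiet),
      error = function(e2)
        DESeq2::DESeq(dds, test = "Wald", fitType = "mean", quiet = quiet)))
  conds <- setdiff(levels(condition), "reference")
  tabs <- lapply(conds, function(cn) {
    res <- DESeq2::results(dds, contrast = c("condition", cn, "reference"),
                           independentFiltering = FALSE, cooksCutoff = FALSE)
    data.frame(gene_id = rownames(res), condition = cn,
               base_mean = res$baseMean, log2fc_raw = res$log2FoldChange,
               lfc_se = res$lfcSE, p = res$pvalue, p_adj = res$padj,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, tabs)
}

#' Shrink log2 fold changes with a zero-centred normal prior
#'
#' Empirical-Bayes shrinkage of the Wald fold-change estimates: treating
#' each raw log2 fold change as normal with its reported standard error,
#' the posterior mean under a zero-centred normal prior is
#' `lfc * tau^2 / (tau^2 + se^2)`. The prior variance `tau^2` is fitted
#' from the data by moment matching (`mean(lfc^2 - se^2)`, floored),
#' unless supplied. Precisely estimated fold changes shrink little; noisy
#' ones shrink strongly, and `|shrunk| <= |raw|` always.
#'
#' @param de_table output of [nb_de_test()].
#' @param prior_sd optional fixed prior standard deviation (log2 units).
#' @return the table with a `log2fc_shrunk` column; the prior sd used is
#'   attached as attribute `"prior_sd"`.
#' @export
shrink_lfc <- function(de_table, prior_sd = NULL) {
  lfc <- de_table$log2fc_raw; se <- de_table$lfc_se
  if (is.null(prior_sd)) {
    ok <- is.finite(lfc) & is.finite(se)
    prior_sd <- sqrt(max(mean(pmax(lfc[ok]^2 - se[ok]^2, 0)), 1e-4))
  }
  stopifnot(prior_sd > 0)
  w <- prior_sd^2 / (prior_sd^2 + se^2)
  w[!is.finite(se)] <- 0
  de_table$log2fc_shrunk <- lfc * w
  attr(de_table, "prior_sd") <- prior_sd
  de_table
}

#' Call differentially expressed genes
#'
#' Flags a gene-condition pair as DE when the BH-adjusted p-value is
#' strictly below `padj_thr` and the absolute log2 fold change strictly
#' exceeds `lfc_thr`; a gene is DE overall when it is DE in at least one
#' condition. The magnitude threshold is applied to the raw Wald estimate
#' by default: the zero-centred normal shrinkage prior pulls genuinely
#' changed genes towards zero in proportion to their standard error, which
#' would make a fixed magnitude cutoff depend on precision rather than
#' effect size. Also returns the per-gene per-condition shrunk-LFC
#' signature matrix of the DE genes, ready for signature clustering.
#'
#' @param de_table output of [nb_de_test()].
#' @param padj_thr adjusted-p threshold (default 0.01).
#' @param lfc_thr absolute log2 fold-change threshold (default 0.5).
#' @param use_shrunk evaluate the LFC threshold on shrunk instead of raw
#'   fold changes.
#' @return a list of class `"de_calls"`: `table` (the de_table with a
#'   `de_flag` column), `gene_flags` (named logical, union over
#'   conditions), `signature` (DE genes x conditions LFC matrix),
#'   `thresholds`.
#' @export
call_de <- function(de_table, padj_thr = 0.01, lfc_thr = 0.5,
                    use_shrunk = FALSE) {
  lfc <- if (use_shrunk && !is.null(de_table$log2fc_shrunk))
    de_table$log2fc_shrunk else de_table$log2fc_raw
  flag <- !is.na(de_table$p_adj) & de_table$p_adj < padj_thr &
    abs(lfc) > lfc_thr
  de_table$de_flag <- flag
  gene_flags <- tapply(flag, de_table$gene_id, any)
  de_genes <- names(gene_flags)[gene_flags]
  conds <- unique(de_table$condition)
  sig <- matrix(NA_real_, length(de_genes), length(conds),
                dimnames = list(de_genes, conds))
  if (length(de_genes)) {
    sub <- de_table[de_table$gene_id %in% de_genes, ]
    sig[cbind(match(sub$gene_id, de_genes),
              match(sub$condition, conds))] <-
      if (is.null(sub$log2fc_shrunk)) sub$log2fc_raw else
        sub$log2fc_shrunk
  }
  structure(list(table = de_table, gene_flags = gene_flags,
                 signature = sig,
                 thresholds = c(padj = padj_thr, lfc = lfc_thr)),
            class = "de_calls")
}

#' @export
print.de_calls <- function(x, ...) {
  cat("DE calls at p_adj <", x$thresholds[["padj"]], "and |log2FC| >",
      x$thresholds[["lfc"]], "\n")
  cat(sum(x$gene_flags), "of", length(x$gene_flags),
      "genes DE in at least one condition\n")
  invisible(x)
}
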