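#' Replicate reliability of an omics layer per condition
#'
#' The reliability of a condition is the geometric mean of the pairwise
#' Pearson correlations between the log2-transformed number fractions of
#' its replicates, computed over the genes detected (positive) in all
#' replicates of that condition. It estimates the fraction of observed
#' variance that is true biological signal rather than replicate noise, and
#' is the de-attenuation denominator of the corrected cross-omics
#' correlation.
#'
#' @param psi number-fraction matrix, genes x samples.
#' @param design sample design (`sample_id`, `condition`, `replicate`).
#' @return a data frame per condition: `condition`, `n_genes` (universe
#'   size), `r` (reliability), plus the pairwise correlations in the
#'   `"pairwise"` attribute.
#' @export
replicate_reliability <- function(psi, design) {
  psi <- as.matrix(psi)
  conds <- unique(design$condition)
  pairwise <- list()
  out <- data.frame(condition = conds, n_genes = NA_integer_, r = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(conds)) {
    ids <- design$sample_id[design$condition == conds[i]]
    cols <- match(ids, colnames(psi))
    if (anyNA(cols)) stop("samples missing from the matrix: ",
                          paste(ids[is.na(cols)], collapse = ", "))
    sub <- psi[, cols, drop = FALSE]
    keep <- rowSums(is.na(sub) | sub <= 0) == 0
    sub <- log2(sub[keep, , drop = FALSE])
    if (ncol(sub) < 2) stop("condition ", conds[i], " has < 2 replicates")
    cc <- stats::cor(sub)
    rho <- cc[upper.tri(cc)]
    if (any(rho <= 0))
      stop("non-positive pairwise replicate correlation in condition ",
           conds[i], " (min = ", signif(min(rho), 3),
           "): geometric mean undefined")
    out$n_genes[i] <- nrow(sub)
    out$r[i] <- exp(mean(log(rho)))
    pairwise[[conds[i]]] <- rho
  }
  attr(out, "pairwise") <- pairwise
  out
}

#' Raw (attenuated) protein-mRNA correlation per condition
#'
#' The uncorrected estimate of the protein-mRNA correlation in a condition
#' is the geometric mean of pairwise Pearson correlations between
#' log2 protein and log2 mRNA number fractions across replicates,
#' restricted to genes detected in all six samples of the condition. The
#' default uses the six replicate pairings with protein replicate index
#' less than or equal to the mRNA index (sixth root of their product);
#' `pairs = "all"` uses all nine pairings instead, which estimates the same
#' quantity.
#'
#' @param psi_p protein number-fraction matrix, genes x samples.
#' @param psi_m mRNA number-fraction matrix, genes x samples.
#' @param design sample design shared by both layers.
#' @param pairs `"triangle"` (six pairings, default) or `"all"` (nine).
#' @return a data frame per condition: `condition`, `n_genes`, `rho_hat`;
#'   pairwise correlations in the `"pairwise"` attribute.
#' @export
raw_cross_correlation <- function(psi_p, psi_m, design,
                                  pairs = c("triangle", "all")) {
  pairs <- match.arg(pairs)
  psi_p <- as.matrix(psi_p); psi_m <- as.matrix(psi_m)
  common <- intersect(rownames(psi_p), rownames(psi_m))
  if (length(common) == 0L) stop("no genes shared between the two layers")
  conds <- unique(design$condition)
  pairwise <- list()
  out <- data.frame(condition = conds, n_genes = NA_integer_,
                    rho_hat = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(conds)) {
    sub <- design[design$condition == conds[i], ]
    sub <- sub[order(sub$replicate), ]
    p <- psi_p[common, match(sub$sample_id, colnames(psi_p)), drop = FALSE]
    m <- psi_m[common, match(sub$sample_id, colnames(psi_m)), drop = FALSE]
    keep <- rowSums(is.na(p) | p <= 0) == 0 & rowSums(is.na(m) | m <= 0) == 0
    p <- log2(p[keep, , drop = FALSE]); m <- log2(m[keep, , drop = FALSE])
    cc <- stats::cor(p, m)              # protein replicates x mRNA replicates
    rho <- if (pairs == "triangle") cc[upper.tri(cc, diag = TRUE)] else c(cc)
    if (any(rho <= 0))
      stop("non-positive protein-mRNA pairwise correlation in condition ",
           conds[i], ": geometric mean undefined")
    out$n_genes[i] <- nrow(p)
    out$rho_hat[i] <- exp(mean(log(rho)))
    pairwise[[conds[i]]] <- cc
  }
  attr(out, "pairwise") <- pairwise
  out
}

#' Attenuation-corrected protein-mRNA correlation
#'
#' Disattenuates the raw correlation by the replicate reliabilities:
#' `R = rho_hat / sqrt(r_P * r_M)`. Because noise only weakens observed
#' correlations, `R` recovers the latent correlation that perfectly
#' reproducible measurements would show; values slightly above 1 can occur
#' by sampling error and are flagged.
#'
#' @param rho_hat raw correlation(s) (from [raw_cross_correlation()]).
#' @param r_p,r_m protein and mRNA reliabilities in (0, 1\].
#' @return numeric vector `R` with attribute `"clamped"` marking values
#'   with |R| > 1.
#' @export
corrected_correlation <- function(rho_hat, r_p, r_m) {
  stopifnot(all(r_p > 0 & r_p <= 1), all(r_m > 0 & r_m <= 1))
  R <- rho_hat / sqrt(r_p * r_m)
  attr(R, "clamped") <- abs(R) > 1
  R
}

#' Full cross-omics reliability report
#'
#' Convenience wrapper combining per-condition protein and mRNA
#' reliabilities, the raw cross-correlation, and the corrected estimate
#' into one table.
#'
#' @inheritParams raw_cross_correlation
#' @return data frame per condition: `condition`, `n_genes`, `r_protein`,
#'   `r_mrna`, `rho_hat`, `R`.
#' @export
reliability_report <- function(psi_p, psi_m, design,
                               pairs = c("triangle", "all")) {
  rp <- replicate_reliability(psi_p, design)
  rm_ <- replicate_reliability(psi_m, design)
  rc <- raw_cross_correlation(psi_p, psi_m, design, pairs = match.arg(pairs))
  data.frame(condition = rp$condition, n_genes = rc$n_genes,
             r_protein = rp$r, r_mrna = rm_$r, rho_hat = rc$rho_hat,
             R = as.numeric(corrected_correlation(rc$rho_hat, rp$r, rm_$r)),
             stringsAsFactors = FALSE)
}

#' Residual log2 protein-to-mRNA ratios
#'
#' `log2(psi_P / psi_M)` per gene and sample, minus the gene's median ratio
#' across samples. Removing the per-gene offset strips the global
#' dependence of the protein-to-mRNA ratio on expression level
#' (post-transcriptional amplification), leaving only the across-sample
#' variation, comparable between genes of very different abundance.
#'
#' @param psi_p,psi_m number-fraction matrices sharing gene ids; samples
#'   are matched by column name.
#' @param min_samples genes with fewer samples carrying both values are
#'   dropped (recorded in the `"dropped"` attribute).
#' @return matrix of residual log2 ratios (NA where either value is
#'   missing), genes x shared samples.
#' @export
residual_ratio <- function(psi_p, psi_m, min_samples = 2L) {
  psi_p <- as.matrix(psi_p); psi_m <- as.matrix(psi_m)
  genes <- intersect(rownames(psi_p), rownames(psi_m))
  samples <- intersect(colnames(psi_p), colnames(psi_m))
  if (length(genes) == 0L || length(samples) == 0L)
    stop("no shared genes/samples between the two layers")
  p <- psi_p[genes, samples, drop = FALSE]
  m <- psi_m[genes, samples, drop = FALSE]
  ratio <- suppressWarnings(log2(p / m))
  ratio[!is.finite(ratio)] <- NA_real_
  enough <- rowSums(!is.na(ratio)) >= min_samples
  dropped <- genes[!enough]
  ratio <- ratio[enough, , drop = FALSE]
  med <- apply(ratio, 1, stats::median, na.rm = TRUE)
  out <- ratio - med
  attr(out, "dropped") <- dropped
  attr(out, "unit") <- "residual_log2_ratio"
  out
}
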