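#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of genes (rows) with Euclidean distance and the
#' Ward.D2 linkage criterion (squared distances inside the Lance-Williams
#' update), cut into `k` clusters. Intended for z-score matrices, where it
#' groups genes by profile shape irrespective of absolute level.
#'
#' @param z matrix, genes x samples, no missing values (typically
#'   [zscore_rows()] output).
#' @param k number of clusters (2 <= k <= number of genes).
#' @return a list of class `"gene_clusters"`: `labels` (named integer
#'   vector), `tree` (the `hclust` object), `k`.
#' @export
hierarchical_clusters <- function(z, k) {
  z <- as.matrix(z)
  if (anyNA(z)) stop("clustering requires a complete matrix")
  if (k < 2 || k > nrow(z)) stop("k must be between 2 and the gene count")
  tree <- stats::hclust(stats::dist(z), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  structure(list(labels = labels, tree = tree, k = k),
            class = "gene_clusters")
}

#' @export
print.gene_clusters <- function(x, ...) {
  cat("Ward.D2 hierarchical clustering,", length(x$labels), "genes in",
      x$k, "clusters\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' PCA of a z-score matrix with per-gene variance decomposition
#'
#' Singular value decomposition of the z-score matrix with genes as
#' observations and samples as variables (no further centring or scaling:
#' rows are already centred). Reports sample-space component scores, gene
#' loadings, the variance explained per component, and for every gene the
#' fraction of its variance captured by PC1,
#' `1 - ||z_i - zhat_i||^2 / ||z_i||^2` with `zhat_i` the rank-1 PC1
#' reconstruction. Each component is oriented so that the sample score of
#' largest magnitude is positive, making downstream sign-dependent labels
#' reproducible.
#'
#' @param z matrix, genes x samples (rows centred, e.g. z-scores).
#' @return a list of class `"pca_structure"`: `scores` (samples x PCs),
#'   `loadings` (genes x PCs), `var_explained`, `pc1_fraction` (per gene),
#'   `d` (singular values).
#' @export
pca_structure <- function(z) {
  z <- as.matrix(z)
  if (ncol(z) < 2) stop("PCA needs at least 2 samples")
  if (anyNA(z)) stop("PCA requires a complete matrix")
  sv <- svd(z)
  ## deterministic orientation: largest-|score| sample positive per PC
  scores <- sv$v %*% diag(sv$d, length(sv$d))
  flip <- vapply(seq_along(sv$d), function(k) {
    s <- scores[, k]; sign(s[which.max(abs(s))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, `*`)
  loadings <- sweep(sv$u, 2, flip, `*`)
  rownames(scores) <- colnames(z)
  rownames(loadings) <- rownames(z)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(sv$d))
  comp_var <- rowSums((loadings * rep(sv$d, each = nrow(loadings)))^2)
  pc1 <- (loadings[, 1L] * sv$d[1L])^2 / pmax(comp_var, .Machine$double.eps)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = sv$d^2 / sum(sv$d^2),
                 pc1_fraction = pc1, d = sv$d),
            class = "pca_structure")
}

#' @export
print.pca_structure <- function(x, digits = 3, ...) {
  cat("PCA of", nrow(x$loadings), "genes x", nrow(x$scores), "samples\n")
  cat("Variance explained:",
      paste0(signif(100 * utils::head(x$var_explained, 5), digits), "%",
             collapse = ", "), "...\n")
  invisible(x)
}

#' Classify genes by their first-principal-component mode
#'
#' Labels a gene `plus` when more than `frac_threshold` of its variance is
#' explained by PC1 and its profile correlates positively with the PC1
#' sample scores, `minus` for a negative correlation, and `none` otherwise.
#' With the deterministic PC orientation of [pca_structure()] the labels
#' identify the two arms of a dominant condition-specific expression mode
#' (such as a nutrient-driven split of the growth media).
#'
#' @param pca a `"pca_structure"` object.
#' @param z the matrix the PCA was computed on (for the correlations); if
#'   omitted, the sign of the PC1 loading is used, which is equivalent.
#' @param frac_threshold minimum PC1 variance fraction (default 0.5).
#' @return factor with levels `plus`, `minus`, `none`, one per gene.
#' @export
wfsp_classify <- function(pca, z = NULL, frac_threshold = 0.5) {
  stopifnot(inherits(pca, "pca_structure"))
  sgn <- if (is.null(z)) {
    sign(pca$loadings[, 1L])
  } else {
    sign(as.numeric(stats::cor(t(as.matrix(z)), pca$scores[, 1L])))
  }
  lab <- ifelse(pca$pc1_fraction > frac_threshold,
                ifelse(sgn > 0, "plus", ifelse(sgn < 0, "minus", "none")),
                "none")
  factor(stats::setNames(lab, rownames(pca$loadings)),
         levels = c("plus", "minus", "none"))
}

#' Barcode lengths: capped relative deviation from the overall median
#'
#' For every gene and condition, the replicate median `x_ij` of the mass
#' fraction is compared with the gene's median over all samples `M_i`
#' through the directed length `l_ij = (x_ij - M_i) / M_i`, clamped to
#' `cap`. Missing observations are imputed to zero before the medians, so
#' a condition where the gene is undetected gets `l = -1`.
#'
#' @param phi mass-fraction matrix, genes x samples (NAs allowed).
#' @param design sample design with `sample_id` and `condition`.
#' @param cap two-element clamp for `l` (default `c(-1, 2)`).
#' @return a list of class `"barcode_matrix"`: `l` (genes x conditions),
#'   `x` (replicate medians), `M` (overall medians), `undefined` (genes
#'   with `M = 0`, whose `l` is NA).
#' @export
barcode_lengths <- function(phi, design, cap = c(-1, 2)) {
  phi <- as.matrix(phi)
  idx <- match(design$sample_id, colnames(phi))
  if (anyNA(idx)) stop("design samples missing from the matrix")
  phi <- phi[, idx, drop = FALSE]
  phi[is.na(phi)] <- 0
  conds <- unique(design$condition)
  x <- vapply(conds, function(cn)
    apply(phi[, design$condition == cn, drop = FALSE], 1, stats::median),
    numeric(nrow(phi)))
  M <- apply(phi, 1, stats::median)
  l <- (x - M) / M
  undefined <- M == 0
  l[undefined, ] <- NA_real_
  l <- pmin(pmax(l, cap[1]), cap[2])
  structure(list(l = l, x = x, M = M,
                 undefined = rownames(phi)[undefined], cap = cap),
            class = "barcode_matrix")
}
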