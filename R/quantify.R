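#' Estimate a growth rate from an optical-density curve
#'
#' Least-squares slope of `log(od)` against time, i.e. the rate of the
#' exponential best fitting the regrowth curve.
#'
#' @param time time points, hours (or a data frame with columns `time` and
#'   `od`).
#' @param od optical densities (> 0).
#' @return the growth rate, per hour.
#' @export
estimate_growth_rate <- function(time, od = NULL) {
  if (is.data.frame(time)) { od <- time$od; time <- time$time }
  stopifnot(length(time) == length(od), length(time) >= 3)
  if (any(od <= 0)) stop("optical densities must be positive")
  unname(coef(stats::lm(log(od) ~ time))[2L])
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed by the standard median-of-ratios
#' procedure (as in DESeq2's `estimateSizeFactors`): each sample's factor is
#' the median, over genes with nonzero counts in every sample, of the ratio
#' of the sample's count to the gene's geometric mean across samples.
#'
#' @param counts raw count matrix, genes x samples.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (!any(apply(counts, 1, function(r) all(r > 0))))
    stop("no gene has nonzero counts in all samples; ",
         "size factors are undefined")
  sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  stats::setNames(sf, colnames(counts))
}

#' Normalise counts by size factors
#'
#' `n = c / S` per sample, making expression comparable across sequencing
#' depths.
#'
#' @param counts raw count matrix, genes x samples.
#' @param sf per-sample size factors (defaults to [size_factors()]).
#' @return matrix of normalised counts with unit attribute
#'   `"normalized_count"`.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(sf) == ncol(counts), all(sf > 0))
  out <- sweep(counts, 2, sf, `/`)
  attr(out, "unit") <- "normalized_count"
  out
}

#' Proteome mass fractions from iBAQ intensities
#'
#' `phi = m_i * B_i / sum_l(m_l * B_l)` per sample: each protein's share of
#' the total proteome mass. Missing intensities contribute zero mass.
#'
#' @param ibaq intensity matrix, proteins x samples (NAs allowed).
#' @param masses per-protein molecular masses, kDa (> 0).
#' @return matrix of mass fractions summing to 1 per sample, with NAs where
#'   the intensity was missing; unit attribute `"mass_fraction"`.
#' @export
mass_fractions <- function(ibaq, masses) {
  ibaq <- as.matrix(ibaq)
  stopifnot(length(masses) == nrow(ibaq), all(masses > 0))
  mb <- ibaq * masses
  tot <- colSums(mb, na.rm = TRUE)
  if (any(tot <= 0)) stop("sample(s) with zero total protein mass: ",
                          paste(colnames(ibaq)[tot <= 0], collapse = ", "))
  out <- sweep(mb, 2, tot, `/`)
  attr(out, "unit") <- "mass_fraction"
  out
}

#' Proteome number fractions from iBAQ intensities
#'
#' `psi_P = B_i / sum_l B_l` per sample: iBAQ is proportional to protein
#' copy number, so this is each protein's share of the total number of
#' protein molecules. Molecular masses play no role.
#'
#' @param ibaq intensity matrix, proteins x samples (NAs allowed).
#' @return matrix of number fractions; unit attribute `"number_fraction"`.
#' @export
number_fractions_protein <- function(ibaq) {
  ibaq <- as.matrix(ibaq)
  tot <- colSums(ibaq, na.rm = TRUE)
  if (any(tot <= 0)) stop("sample(s) with zero total intensity")
  out <- sweep(ibaq, 2, tot, `/`)
  attr(out, "unit") <- "number_fraction"
  out
}

#' Transcriptome number fractions from normalised counts
#'
#' `psi_M = (n_i / l_i) / sum_l(n_l / l_l)` per sample: dividing normalised
#' counts by transcript length converts read shares into molecule shares.
#'
#' @param norm_counts normalised count matrix, genes x samples.
#' @param lengths per-gene transcript lengths, nt (> 0).
#' @return matrix of number fractions; unit attribute `"number_fraction"`.
#' @export
number_fractions_rna <- function(norm_counts, lengths) {
  norm_counts <- as.matrix(norm_counts)
  stopifnot(length(lengths) == nrow(norm_counts), all(lengths > 0))
  x <- norm_counts / lengths
  tot <- colSums(x, na.rm = TRUE)
  if (any(tot <= 0)) stop("sample(s) with zero total molecule count")
  out <- sweep(x, 2, tot, `/`)
  attr(out, "unit") <- "number_fraction"
  out
}

#' Filter genes by detection pattern
#'
#' Drops rows that fail a detection criterion (an observation counts as
#' detected when it is neither `NA` nor zero):
#' `"all_samples"` requires detection everywhere, `"all_replicates_within_any_condition"`
#' keeps genes detected in every replicate of at least one condition, and
#' `"at_least_one"` requires a single detection.
#'
#' @param mat expression matrix, genes x samples.
#' @param mode detection criterion.
#' @param design sample design (needed for the per-condition mode).
#' @return the filtered matrix; the dropped gene ids are attached as
#'   attribute `"removed"`.
#' @export
filter_detected <- function(mat,
                            mode = c("all_samples",
                                     "all_replicates_within_any_condition",
                                     "at_least_one"),
                            design = NULL) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  det <- !is.na(mat) & mat != 0
  keep <- switch(mode,
    all_samples = rowSums(det) == ncol(mat),
    at_least_one = rowSums(det) > 0,
    all_replicates_within_any_condition = {
      if (is.null(design)) stop("the per-condition mode needs a design")
      idx <- split(match(design$sample_id, colnames(mat)), design$condition)
      hits <- vapply(idx, function(cols)
        rowSums(det[, cols, drop = FALSE]) == length(cols), logical(nrow(mat)))
      rowSums(hits) > 0
    })
  out <- mat[keep, , drop = FALSE]
  attr(out, "unit") <- attr(mat, "unit")
  attr(out, "removed") <- rownames(mat)[!keep]
  out
}

#' Row-wise z-scores
#'
#' `(y - mean) / sd` per row, with the sample (n - 1) standard deviation,
#' normalising away differences in absolute expression level before
#' clustering or PCA.
#'
#' @param mat expression matrix, genes x samples, without missing values.
#' @param drop_constant drop zero-variance rows with a warning instead of
#'   erroring.
#' @return matrix of z-scores (row mean 0, sd 1); unit attribute
#'   `"zscore"`.
#' @export
zscore_rows <- function(mat, drop_constant = FALSE) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("z-scoring requires a complete matrix")
  mu <- rowMeans(mat)
  sd <- sqrt(rowSums((mat - mu)^2) / (ncol(mat) - 1))
  if (any(sd == 0)) {
    if (!drop_constant)
      stop("constant row(s): ",
           paste(utils::head(rownames(mat)[sd == 0]), collapse = ", "))
    warning(sum(sd == 0), " constant row(s) dropped")
    keep <- sd > 0
    mat <- mat[keep, , drop = FALSE]; mu <- mu[keep]; sd <- sd[keep]
  }
  out <- (mat - mu) / sd
  attr(out, "unit") <- "zscore"
  out
}
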