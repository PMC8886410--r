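#' Fit growth laws to every gene of an expression matrix
#'
#' Applies the repeated-median linear model ([rmlm()]) gene by gene to
#' expression (normalised counts or proteome fractions) against the
#' per-sample growth rates, computes the FC statistic, fit statistics
#' (R-squared, normalised SSR, F-test p-value), and assigns each gene to
#' the R, P or Q sector by tail-based fdr ([assign_sectors()]). Genes with
#' missing observations are fitted on the available points; genes with
#' fewer than `min_points` usable points (or no growth-rate spread) get NA
#' statistics and sector Q.
#'
#' @param mat expression matrix, genes x samples (NAs allowed).
#' @param design sample design with `sample_id` and `mu` columns; samples
#'   are matched to matrix columns by id.
#' @param mu_max growth-rate range end for the FC statistic, per hour.
#' @param fdr_threshold tail-based fdr cutoff for R/P sector membership.
#' @param lfdr_threshold local fdr cutoff for the confident flag.
#' @param eta0 optional fixed null proportion for [tail_fdr()].
#' @param min_points minimum observations per gene.
#' @return a data frame of class `"growth_law_fits"`, one row per input
#'   gene: `gene_id`, `n_points`, `slope`, `intercept`, `fc`, `r_squared`,
#'   `ssr_norm`, `p_value`, `q_value`, `lfdr`, `sector`, `confident`.
#' @export
fit_growth_laws <- function(mat, design, mu_max = 0.3, fdr_threshold = 0.1,
                            lfdr_threshold = 0.1, eta0 = NULL,
                            min_points = 3L) {
  mat <- as.matrix(mat)
  idx <- match(design$sample_id, colnames(mat))
  if (anyNA(idx)) stop("design samples missing from the matrix: ",
                       paste(design$sample_id[is.na(idx)], collapse = ", "))
  mat <- mat[, idx, drop = FALSE]
  mu <- design$mu
  ng <- nrow(mat)
  out <- data.frame(gene_id = rownames(mat), n_points = 0L,
                    slope = NA_real_, intercept = NA_real_, fc = NA_real_,
                    r_squared = NA_real_, ssr_norm = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  for (g in seq_len(ng)) {
    y <- mat[g, ]
    ok <- is.finite(y)
    out$n_points[g] <- sum(ok)
    if (sum(ok) < min_points || diff(range(mu[ok])) < 1e-12) next
    fit <- rmlm.default(mu[ok], y[ok])
    s <- summary(fit, mu_max = mu_max)
    out$slope[g] <- fit$coefficients[[2L]]
    out$intercept[g] <- fit$coefficients[[1L]]
    out$fc[g] <- s$fc
    out$r_squared[g] <- s$r.squared
    out$ssr_norm[g] <- s$ssr_norm
    out$p_value[g] <- s$p.value
  }
  sec <- assign_sectors(out$p_value, out$slope,
                        fdr_threshold = fdr_threshold,
                        lfdr_threshold = lfdr_threshold, eta0 = eta0)
  out$q_value <- sec$q
  out$lfdr <- sec$lfdr
  out$sector <- sec$sector
  out$sector[is.na(out$p_value)] <- "Q"
  out$confident <- sec$confident
  attr(out, "mu_max") <- mu_max
  class(out) <- c("growth_law_fits", "data.frame")
  out
}

#' @export
print.growth_law_fits <- function(x, ...) {
  cat("Growth-law fits for", nrow(x), "genes (mu_max =",
      attr(x, "mu_max"), "per h)\n")
  tab <- table(x$sector)
  cat("Sectors: R =", tab[["R"]], " P =", tab[["P"]], " Q =", tab[["Q"]],
      "  (confident:", sum(x$confident, na.rm = TRUE), ")\n\n")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more genes\n")
  invisible(x)
}

#' Summed expression profile of a gene set
#'
#' Per-sample column sums restricted to the set members present in the
#' matrix. On fraction-unit matrices this gives the share of the proteome
#' (or transcriptome) allocated to the set, the quantity whose growth law
#' summarises a whole pathway or sector.
#'
#' @param mat expression matrix, genes x samples.
#' @param genes character vector of member gene ids.
#' @return named per-sample sums; members found/missing are reported in the
#'   `"members"` attribute.
#' @export
gene_set_sums <- function(mat, genes) {
  mat <- as.matrix(mat)
  present <- intersect(genes, rownames(mat))
  if (length(present) == 0L) stop("no gene of the set is in the matrix")
  out <- colSums(mat[present, , drop = FALSE], na.rm = TRUE)
  attr(out, "members") <- list(present = present,
                               missing = setdiff(genes, present))
  out
}

#' Bootstrap confidence band for a growth law
#'
#' Resamples the (growth rate, expression) pairs with replacement,
#' refits the repeated-median line on every resample, and reports pointwise
#' 2.5/97.5 percentile bands of the predictions over a growth-rate grid
#' together with the bootstrap mean and sd of the FC statistic. Resamples
#' without at least two distinct growth rates are redrawn (counted in the
#' output).
#'
#' @param x growth rates (or an `"rmlm"` object).
#' @param y expression values.
#' @param n_boot number of bootstrap resamples.
#' @param grid growth-rate grid for the band (default 101 points on
#'   \[0, 0.3\]).
#' @param level band coverage (default 0.95).
#' @param mu_max growth-rate range end for the FC statistic.
#' @param seed optional integer seed.
#' @param parm,object,... for the `confint` method: see [confint()].
#' @return a list of class `"growth_law_band"`: `mu` (grid), `predicted`
#'   (full-data fit), `lower`, `upper`, `fc`, `fc_mean`, `fc_sd`,
#'   `boot_coefficients`, `n_redraws`.
#' @export
bootstrap_growth_law <- function(x, y = NULL, n_boot = 1000,
                                 grid = seq(0, 0.3, length.out = 101),
                                 level = 0.95, mu_max = 0.3, seed = NULL) {
  if (inherits(x, "rmlm")) { y <- x$y; x <- x$x }
  stopifnot(length(x) == length(y), length(x) >= 4, n_boot >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  full <- rmlm.default(x, y)
  cf <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL,
                                                    c("intercept", "slope")))
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      if (diff(range(x[i])) > 1e-12) break
      redraws <- redraws + 1L
    }
    cf[b, ] <- rev(repeated_median(x[i], y[i]))
  }
  pred <- cf[, "intercept"] + outer(cf[, "slope"], grid)  # n_boot x grid
  alpha <- (1 - level) / 2
  qs <- apply(pred, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  fc <- fold_change(cf[, "slope"], cf[, "intercept"], mu_max = mu_max)
  structure(list(mu = grid,
                 predicted = full$coefficients[[1L]] +
                   full$coefficients[[2L]] * grid,
                 lower = qs[1L, ], upper = qs[2L, ],
                 fc = fold_change(full, mu_max = mu_max),
                 fc_mean = mean(fc, na.rm = TRUE),
                 fc_sd = stats::sd(fc, na.rm = TRUE),
                 boot_coefficients = cf, n_redraws = redraws,
                 level = level),
            class = "growth_law_band")
}

#' @export
print.growth_law_band <- function(x, digits = 4, ...) {
  cat("Bootstrap growth-law band (", nrow(x$boot_coefficients),
      " resamples, ", x$level * 100, "% pointwise)\n", sep = "")
  cat("FC = ", signif(x$fc, digits), "  (bootstrap ",
      signif(x$fc_mean, digits), " +/- ", signif(x$fc_sd, digits), ")\n",
      sep = "")
  invisible(x)
}

#' Predicted ratio of two fitted growth laws
#'
#' Pointwise ratio of the two fitted lines over a growth-rate grid, e.g.
#' the predicted stoichiometry of two pathway mass fractions as a function
#' of growth rate. Grid points where the denominator line is (numerically)
#' zero are set to NA and flagged.
#'
#' @param fit_a,fit_b `"rmlm"` objects (or `(intercept, slope)` vectors).
#' @param grid growth-rate grid.
#' @param tol denominator magnitude below which the ratio is undefined.
#' @return data frame with columns `mu`, `ratio`, `undefined`.
#' @export
ratio_trend <- function(fit_a, fit_b, grid = seq(0, 0.3, length.out = 101),
                        tol = 1e-12) {
  cfa <- if (inherits(fit_a, "rmlm")) fit_a$coefficients else fit_a
  cfb <- if (inherits(fit_b, "rmlm")) fit_b$coefficients else fit_b
  num <- cfa[[1L]] + cfa[[2L]] * grid
  den <- cfb[[1L]] + cfb[[2L]] * grid
  bad <- abs(den) < tol
  ratio <- num / den
  ratio[bad] <- NA_real_
  data.frame(mu = grid, ratio = ratio, undefined = bad)
}
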