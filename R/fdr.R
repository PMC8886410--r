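#' Tail-based and local false discovery rates from p-values
#'
#' Empirical-Bayes FDR estimation on a vector of p-values. The null
#' proportion `eta0` is estimated by censoring: for a cutoff lambda the
#' fraction of p-values above lambda, divided by `1 - lambda`, estimates the
#' null proportion; the estimate is stabilised by taking the median over a
#' grid of cutoffs in the upper half of the p distribution (capped at 1).
#' The tail-based fdr (q-value) at a p-value is
#' `q(p) = eta0 * p / ECDF(p)`, made monotone non-decreasing in p and capped
#' at 1; with `eta0 = 1` this is exactly the Benjamini-Hochberg step-up
#' adjustment. The local fdr is `eta0 / f(p)` where `f` is the Grenander
#' (decreasing, least-concave-majorant) estimate of the p-value density.
#'
#' With fewer than `min_n` p-values the density estimate is unreliable: the
#' function falls back to Benjamini-Hochberg (`eta0 = 1`, `lfdr = q`) with a
#' warning.
#'
#' @param p numeric vector of p-values in \[0, 1\]; NAs are propagated.
#' @param eta0 optional fixed null proportion; `NULL` (default) estimates it.
#' @param min_n minimum number of p-values for the empirical-null machinery.
#' @return a list with `q`, `lfdr` (same length as `p`), the estimated
#'   `eta0`, and `method` (`"empirical"` or `"bh"`).
#' @export
tail_fdr <- function(p, eta0 = NULL, min_n = 50L) {
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  n <- length(pv)
  q <- lfdr <- rep(NA_real_, length(p))
  if (n < min_n) {
    warning("fewer than ", min_n,
            " p-values: falling back to Benjamini-Hochberg (eta0 = 1)")
    qv <- stats::p.adjust(pv, method = "BH")
    q[ok] <- qv; lfdr[ok] <- qv
    return(list(q = q, lfdr = lfdr, eta0 = 1, method = "bh"))
  }
  if (is.null(eta0)) {
    lam <- seq(0.4, 0.8, by = 0.05)
    cand <- vapply(lam, function(l) mean(pv > l) / (1 - l), numeric(1))
    eta0 <- min(1, max(stats::median(cand), 1 / n))
  }
  ord <- order(pv)
  ranks <- rank(pv, ties.method = "max")   # ECDF(p) = ranks / n
  q_raw <- eta0 * pv * n / ranks
  ## enforce monotonicity in p (step-up, as in BH)
  qs <- q_raw[ord]
  qs <- rev(cummin(rev(qs)))
  qv <- numeric(n); qv[ord] <- pmin(qs, 1)
  fhat <- grenander_density(pv)
  lf <- pmin(eta0 / fhat, 1)
  q[ok] <- qv; lfdr[ok] <- lf
  list(q = q, lfdr = lfdr, eta0 = eta0, method = "empirical")
}

## Grenander estimator of a decreasing density on [0, 1]: the slope of the
## least concave majorant of the ECDF, evaluated at each observation.
grenander_density <- function(p) {
  n <- length(p)
  sp <- sort(unique(p))
  cnt <- tabulate(match(sort(p), sp))
  xs <- c(0, sp, if (max(sp) < 1) 1)
  ys <- c(0, cumsum(cnt) / n, if (max(sp) < 1) 1)
  m <- length(xs)
  ## upper concave hull scan (slopes must be non-increasing)
  hull <- integer(m); hull[1] <- 1L; h <- 1L
  for (k in 2:m) {
    while (h >= 2L) {
      s1 <- (ys[hull[h]] - ys[hull[h - 1L]]) / (xs[hull[h]] - xs[hull[h - 1L]])
      s2 <- (ys[k] - ys[hull[h]]) / (xs[k] - xs[hull[h]])
      if (s2 > s1) h <- h - 1L else break
    }
    h <- h + 1L; hull[h] <- k
  }
  hull <- hull[seq_len(h)]
  hx <- xs[hull]; hy <- ys[hull]
  slopes <- diff(hy) / diff(hx)
  ## evaluate at each p: slope of the segment whose interval contains p
  idx <- findInterval(p, hx, left.open = TRUE, all.inside = TRUE)
  pmax(slopes[idx], .Machine$double.eps)
}

#' Assign genes to growth-rate sectors
#'
#' Classifies genes by the sign and significance of their fitted growth-law
#' slope: R (positively correlated with growth rate) if the slope is
#' positive and the tail-based fdr is below `fdr_threshold`; P (negatively
#' correlated) if the slope is negative at the same significance; Q
#' otherwise. Genes with local fdr below `lfdr_threshold` are flagged as
#' confident calls.
#'
#' @param p p-values of the per-gene growth-law fits.
#' @param slope fitted slopes (same length).
#' @param fdr_threshold tail-based fdr cutoff for R/P membership.
#' @param lfdr_threshold local fdr cutoff for the confident flag.
#' @param eta0 optional fixed null proportion passed to [tail_fdr()].
#' @return a data frame with columns `q`, `lfdr`, `sector` (factor with
#'   levels R, P, Q) and `confident`.
#' @export
assign_sectors <- function(p, slope, fdr_threshold = 0.1,
                           lfdr_threshold = 0.1, eta0 = NULL) {
  stopifnot(length(p) == length(slope))
  fd <- tail_fdr(p, eta0 = eta0)
  sig <- !is.na(fd$q) & fd$q < fdr_threshold
  sector <- factor(ifelse(sig & slope > 0, "R",
                          ifelse(sig & slope < 0, "P", "Q")),
                   levels = c("R", "P", "Q"))
  data.frame(q = fd$q, lfdr = fd$lfdr, sector = sector,
             confident = !is.na(fd$lfdr) & fd$lfdr < lfdr_threshold)
}
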