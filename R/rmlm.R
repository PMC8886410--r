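#' Repeated-median linear model (Siegel robust regression)
#'
#' Fits a straight line `y = a * mu + b` by the repeated-median estimator:
#' from every observation i a line is drawn to each other observation j,
#' giving pairwise slopes and y-intercepts; the median over j is taken per
#' point, and the median of those per-point medians gives the fitted slope
#' and intercept. The estimator has a breakdown point of about 50%, so it
#' tolerates genes that are strongly enriched in a subset of conditions on
#' top of their growth-rate trend.
#'
#' Pairs closer than `tie_tol` in the predictor are excluded from a point's
#' pairwise medians (their slope is undefined). Even-length medians use the
#' usual midpoint convention.
#'
#' @param formula a formula of the form `y ~ mu` (one predictor, intercept
#'   implied).
#' @param data a data frame containing the variables in `formula`.
#' @param x,y numeric vectors of predictor (growth rate, per hour) and
#'   response (expression) for the default method.
#' @param tie_tol pairs with predictor difference below this are skipped.
#' @param ... unused.
#' @return an object of class `"rmlm"` with components `coefficients`
#'   (intercept, slope), `fitted.values`, `residuals`, `x`, `y`, `n`, `call`.
#' @examples
#' fit <- rmlm(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 100))
#' coef(fit)  # slope 1, intercept 0: the outlier is ignored
#' @seealso [fold_change()], [summary.rmlm()], [bootstrap_growth_law()]
#' @export
rmlm <- function(x, ...) UseMethod("rmlm")

#' @rdname rmlm
#' @export
rmlm.formula <- function(formula, data = environment(formula),
                         tie_tol = 1e-12, ...) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L)
    stop("'formula' must have exactly one predictor, e.g. y ~ mu")
  fit <- rmlm.default(mf[[2L]], mf[[1L]], tie_tol = tie_tol)
  fit$call <- match.call()
  fit
}

#' @rdname rmlm
#' @export
rmlm.default <- function(x, y, tie_tol = 1e-12, ...) {
  keep <- is.finite(x) & is.finite(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L) stop("rmlm needs at least 3 finite (x, y) pairs")
  if (diff(range(x)) < tie_tol) stop("all predictor values are identical")
  cf <- repeated_median(x, y, tie_tol)
  fitted <- cf[["intercept"]] + cf[["slope"]] * x
  structure(list(coefficients = c(`(Intercept)` = cf[["intercept"]],
                                  slope = cf[["slope"]]),
                 fitted.values = fitted, residuals = y - fitted,
                 x = x, y = y, n = n, call = match.call()),
            class = "rmlm")
}

## Pairwise slopes s_ij = (y_j - y_i)/(x_j - x_i) and intercepts
## t_ij = (x_j y_i - x_i y_j)/(x_j - x_i); median over j per point i,
## then median over i.
repeated_median <- function(x, y, tie_tol = 1e-12) {
  n <- length(x)
  dx <- outer(x, x, "-")            # dx[i, j] = x_i - x_j
  ok <- abs(dx) > tie_tol
  s <- (outer(y, y, "-")) / dx      # slope of line through i and j
  t <- (outer(x, y) - outer(y, x)) / dx  # t[i,j] = (x_i y_j - y_i x_j)/(x_i - x_j)
  med_i_s <- numeric(n); med_i_t <- numeric(n)
  for (i in seq_len(n)) {
    j <- ok[i, ]
    if (!any(j)) { med_i_s[i] <- NA_real_; med_i_t[i] <- NA_real_; next }
    med_i_s[i] <- stats::median(s[i, j])
    med_i_t[i] <- stats::median(t[i, j])
  }
  c(slope = stats::median(med_i_s, na.rm = TRUE),
    intercept = stats::median(med_i_t, na.rm = TRUE))
}

#' @export
print.rmlm <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Repeated-median linear model\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat("\nCoefficients:\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.rmlm <- function(object, ...) object$coefficients

#' @export
fitted.rmlm <- function(object, ...) object$fitted.values

#' @export
residuals.rmlm <- function(object, ...) object$residuals

#' @export
predict.rmlm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  x <- if (is.data.frame(newdata)) newdata[[1L]] else as.numeric(newdata)
  object$coefficients[[1L]] + object$coefficients[[2L]] * x
}

#' @export
simulate.rmlm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim,
                   object$fitted.values +
                     sample(object$residuals, object$n, replace = TRUE),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' Growth-law fold change of a fitted line
#'
#' A scale-free measure of growth-rate dependence: the rise of the fitted
#' line over `[0, mu_max]` divided by its value at the midpoint
#' `mu_max / 2`,
#' `FC = (y(mu_max) - y(0)) / y(mu_max / 2) = mu_max / (mu_max / 2 + b / a)`.
#' A gene whose expression is proportional to the growth rate has FC = 2; a
#' flat gene has FC = 0. FC is invariant to rescaling the response by any
#' positive constant, so transcripts and proteins of very different absolute
#' abundance can be compared.
#'
#' @param slope,intercept fitted line coefficients, or an `"rmlm"` object
#'   passed as `slope`.
#' @param mu_max upper end of the growth-rate range, per hour (default 0.3).
#' @return the FC value; 0 when the slope is 0; `NA` (with a warning) when
#'   the line crosses zero exactly at the midpoint, where FC is undefined.
#' @examples
#' fold_change(1, 0)        # 2: pure proportionality
#' fold_change(-1, 0.3)     # -2
#' @export
fold_change <- function(slope, intercept = NULL, mu_max = 0.3) {
  if (inherits(slope, "rmlm")) {
    intercept <- slope$coefficients[[1L]]
    slope <- slope$coefficients[[2L]]
  }
  stopifnot(length(slope) == length(intercept), mu_max > 0)
  fc <- ifelse(slope == 0, 0, mu_max / (0.5 * mu_max + intercept / slope))
  mid <- 0.5 * mu_max * slope + intercept
  bad <- slope != 0 & mid == 0
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad, na.rm = TRUE),
            " line(s) cross zero at mu_max/2; FC undefined, set to NA")
    fc[which(bad)] <- NA_real_
  }
  fc
}

#' Fit statistics for a repeated-median growth law
#'
#' Computes R-squared about the mean of the response,
#' `R2 = 1 - sum(r^2) / sum((y - mean(y))^2)`, the normalised sum of squared
#' residuals `SSR_norm = sum(r^2) / ((N - 1) * mean(y))`, and a p-value from
#' the F(1, N - 2) distribution at `F = R2 / (1 - R2) * (N - 2)`. R-squared
#' of a robust fit can be negative; it is clamped at 0 for the F statistic
#' and such fits get p = 1.
#'
#' @param object an `"rmlm"` fit.
#' @param mu_max growth-rate range end used for the FC statistic.
#' @return `summary.rmlm` returns an object of class `"summary.rmlm"` with
#'   `coefficients`, `n`, `r.squared`, `ssr_norm`, `p.value` and `fc`.
#' @export
summary.rmlm <- function(object, mu_max = 0.3, ...) {
  r <- object$residuals; y <- object$y; n <- object$n
  ssr <- sum(r^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  ybar <- mean(y)
  ssr_norm <- if (ybar != 0) ssr / ((n - 1) * ybar) else NA_real_
  p <- rmlm_p_value(r2, n)
  structure(list(call = object$call, coefficients = object$coefficients,
                 n = n, r.squared = r2, ssr_norm = ssr_norm, p.value = p,
                 fc = fold_change(object$coefficients[[2L]],
                                  object$coefficients[[1L]], mu_max),
                 mu_max = mu_max),
            class = "summary.rmlm")
}

rmlm_p_value <- function(r2, n) {
  if (is.na(r2) || n < 3L) return(NA_real_)
  r2c <- max(r2, 0)
  if (r2c <= 0) return(1)
  if (r2c >= 1) return(0)
  stats::pf(r2c / (1 - r2c) * (n - 2), 1, n - 2, lower.tail = FALSE)
}

#' @export
print.summary.rmlm <- function(x, digits = max(3L, getOption("digits") - 3L),
                               ...) {
  cat("Repeated-median linear model (N =", x$n, "points)\n")
  cat("\nCoefficients:\n"); print(signif(x$coefficients, digits))
  cat("\nR-squared: ", formatC(x$r.squared, digits = digits),
      "   SSR_norm: ", formatC(x$ssr_norm, digits = digits),
      "   p-value: ", format.pval(x$p.value, digits = digits), "\n", sep = "")
  cat("FC (mu_max = ", x$mu_max, "): ", formatC(x$fc, digits = digits),
      "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname bootstrap_growth_law
confint.rmlm <- function(object, parm, level = 0.95, n_boot = 1000,
                         seed = NULL, ...) {
  band <- bootstrap_growth_law(object$x, object$y, n_boot = n_boot,
                               grid = range(object$x), level = level,
                               seed = seed)
  ci <- rbind(stats::quantile(band$boot_coefficients[, "intercept"],
                              c((1 - level) / 2, 1 - (1 - level) / 2)),
              stats::quantile(band$boot_coefficients[, "slope"],
                              c((1 - level) / 2, 1 - (1 - level) / 2)))
  rownames(ci) <- c("(Intercept)", "slope")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
plot.rmlm <- function(x, band = NULL, ...) {
  plot(x$x, x$y, xlab = "growth rate (per h)", ylab = "expression", ...)
  graphics::abline(a = x$coefficients[[1L]], b = x$coefficients[[2L]])
  if (!is.null(band)) {
    graphics::lines(band$mu, band$lower, lty = 2)
    graphics::lines(band$mu, band$upper, lty = 2)
  }
  invisible(x)
}
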