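# Builds a one-condition toy: latent log2 profiles plus replicate noise,
# converted to per-sample fractions (the normalisation shifts log2 values
# by a per-sample constant, which Pearson correlations ignore).
toy_fractions <- function(latent_log2, noise_sd, n_rep = 3, prefix = "c1") {
  n <- length(latent_log2)
  m <- sapply(seq_len(n_rep), function(k)
    2^(latent_log2 + rnorm(n, 0, noise_sd)))
  m <- sweep(m, 2, colSums(m), `/`)
  dimnames(m) <- list(paste0("g", seq_len(n)),
                      paste0(prefix, "_r", seq_len(n_rep)))
  m
}
toy_design <- function(prefix = "c1", n_rep = 3)
  data.frame(sample_id = paste0(prefix, "_r", seq_len(n_rep)),
             condition = prefix, replicate = seq_len(n_rep), mu = 0.2)

test_that("reliability is 1 for identical replicates and matches the
           analytic attenuation ratio under noise", {
  set.seed(1)
  lat <- rnorm(800, 0, 1.5)
  ident <- toy_fractions(lat, 0)
  d <- toy_design()
  expect_equal(replicate_reliability(ident, d)$r, 1, tolerance = 1e-12)

  # r ~= var(signal) / (var(signal) + var(noise)) on the log2 scale
  noise_sd <- 0.4
  rs <- replicate(20, {
    psi <- toy_fractions(rnorm(800, 0, 1.5), noise_sd)
    replicate_reliability(psi, d)$r
  })
  expect_equal(mean(rs), 1.5^2 / (1.5^2 + noise_sd^2), tolerance = 0.02)

  # r equals the geometric mean of its reported pairwise correlations
  psi <- toy_fractions(lat, 0.3)
  rep_out <- replicate_reliability(psi, d)
  expect_equal(rep_out$r,
               exp(mean(log(attr(rep_out, "pairwise")$c1))),
               tolerance = 1e-12)
})

test_that("raw cross-correlation attenuates and both pairings agree", {
  set.seed(2)
  d <- toy_design()
  lat <- rnorm(1000, 0, 1.5)
  ident <- toy_fractions(lat, 0)          # identical replicates
  expect_equal(raw_cross_correlation(ident, ident, d)$rho_hat, 1,
               tolerance = 1e-12)
  psi_p <- toy_fractions(lat, 0.3)

  psi_m <- toy_fractions(lat, 0.1)
  six <- raw_cross_correlation(psi_p, psi_m, d, pairs = "triangle")
  nine <- raw_cross_correlation(psi_p, psi_m, d, pairs = "all")
  expect_equal(six$rho_hat, nine$rho_hat, tolerance = 0.01)
  expect_lt(six$rho_hat, 1)             # attenuated below the latent 1
  # six-term definition verified against direct enumeration
  cc <- attr(six, "pairwise")$c1
  expect_equal(six$rho_hat,
               prod(cc[upper.tri(cc, diag = TRUE)])^(1 / 6),
               tolerance = 1e-12)

  ind <- toy_fractions(rnorm(1000), 0.1)
  expect_error(raw_cross_correlation(psi_p, ind, d), "non-positive")
})

test_that("the Spearman correction de-attenuates correlations", {
  expect_equal(as.numeric(corrected_correlation(0.6, 0.9, 0.8)),
               0.6 / sqrt(0.72), tolerance = 1e-12)
  expect_equal(as.numeric(corrected_correlation(0.55, 1, 1)), 0.55)
  expect_error(corrected_correlation(0.5, 1.2, 0.9))

  # planted latent correlation 0.8: raw biased low, corrected on target
  set.seed(3)
  d <- toy_design()
  runs <- t(replicate(30, {
    n <- 800
    xm <- rnorm(n, 0, 1.5)
    xp <- 0.8 * xm + sqrt(1 - 0.8^2) * rnorm(n, 0, 1.5)
    psi_p <- toy_fractions(xp, 0.45)
    psi_m <- toy_fractions(xm, 0.2)
    rep <- reliability_report(psi_p, psi_m, d)
    c(raw = rep$rho_hat, R = rep$R)
  }))
  expect_lt(mean(runs[, "raw"]), 0.78)
  expect_equal(mean(runs[, "R"]), 0.8, tolerance = 0.03)
})

test_that("residual ratios remove per-gene offsets", {
  set.seed(4)
  d <- toy_design()
  lat <- rnorm(50, 0, 1)
  psi_m <- toy_fractions(lat, 0)
  psi_p <- psi_m * 2^rnorm(50, 0, 2)       # per-gene amplification only
  psi_p <- sweep(psi_p, 2, colSums(psi_p), `/`)
  rr <- residual_ratio(psi_p, psi_m)
  expect_true(all(abs(apply(rr, 1, median)) < 1e-9))
  # constant per-gene ratio across samples leaves zero residuals
  expect_lt(max(abs(rr)), 0.2)

  # doubling the protein value in one sample adds +1 to that residual
  psi_p2 <- psi_p
  psi_p2[1, 2] <- 2 * psi_p2[1, 2]
  rr2 <- residual_ratio(psi_p2, psi_m)
  expect_equal(rr2[1, 2] - rr[1, 2], 1, tolerance = 1e-9)
})
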