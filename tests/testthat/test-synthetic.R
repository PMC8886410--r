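test_that("design generation respects shape, range, and determinism", {
  d <- simulate_design(8, 3, 0.05, 0.28, 0.02, seed = 1)
  expect_equal(nrow(d), 24)
  expect_false(anyDuplicated(d[c("condition", "replicate")]) > 0)
  expect_true(all(d$mu > 0.05 * exp(-4 * 0.02) & d$mu < 0.28 * exp(4 * 0.02)))

  d0 <- simulate_design(2, 1, 0.1, 0.2, 0, seed = 0)
  expect_equal(d0$mu, c(0.1, 0.2))

  expect_identical(simulate_design(seed = 7), simulate_design(seed = 7))
  expect_error(simulate_design(2, 3, -0.1, 0.2), "0 < mu_low")
})

test_that("gene truth plants sectors and exact FC targets", {
  tr <- simulate_gene_truth(1000, c(R = 0.3, P = 0.25, Q = 0.45), seed = 2)
  expect_equal(as.numeric(table(tr$sector_true)), c(300, 250, 450))
  expect_true(all(tr$slope_true[tr$sector_true == "R"] > 0))
  expect_true(all(tr$slope_true[tr$sector_true == "P"] < 0))
  expect_true(all(tr$slope_true[tr$sector_true == "Q"] == 0))

  # planted (slope, intercept) reproduce the drawn FC through the
  # fold-change statistic itself
  rp <- tr$sector_true != "Q"
  expect_equal(fold_change(tr$slope_true[rp], tr$intercept_true[rp]),
               tr$fc_true[rp], tolerance = 1e-12)
  # FC = 2 corresponds to pure proportionality (zero intercept)
  tr2 <- simulate_gene_truth(10, c(R = 1, P = 0, Q = 0), fc_range = c(2, 2),
                             seed = 3)
  expect_equal(tr2$intercept_true, rep(0, 10), tolerance = 1e-12)

  expect_error(simulate_gene_truth(10, c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("noiseless RNA counts equal the rounded planted means", {
  d <- make_design(seed = 4)
  tr <- simulate_gene_truth(50, dispersion = 0, condition_effect_frac = 0.3,
                            seed = 4)
  lib <- rep(1e6, 24)
  cnt <- simulate_rna_counts(tr, d, library_size = lib, seed = 4)
  # independent recomputation of the generative mean
  ce <- attr(tr, "condition_effects")
  rel <- (outer(tr$slope_true, d$mu) + tr$intercept_true) *
    2^ce[, match(d$condition, colnames(ce))] * (tr$length / 1500)
  expect_equal(unname(cnt), unname(round(rel * 1e6)))
})

test_that("library size scales expected column sums linearly", {
  d <- make_design(seed = 5)
  tr <- simulate_gene_truth(100, dispersion = 0, seed = 5)
  lib <- rep(1e6, 24); lib[3] <- 2e6
  cnt <- simulate_rna_counts(tr, d, library_size = lib, seed = 5)
  base <- simulate_rna_counts(tr, d, library_size = rep(1e6, 24), seed = 5)
  expect_equal(sum(cnt[, 3]) / sum(base[, 3]), 2, tolerance = 1e-3)

  # Monte-Carlo: mean NB column sums match the planted totals within 2%
  tr2 <- simulate_gene_truth(200, dispersion = 0.05, seed = 6)
  sums <- rowMeans(sapply(1:100, function(s)
    colSums(simulate_rna_counts(tr2, d, library_size = rep(1e5, 24),
                                seed = s))))
  expected <- colSums(truth_matrix(tr2, d) * (tr2$length / 1500) * 1e5)
  expect_equal(unname(sums), unname(expected), tolerance = 0.02)
})

test_that("protein simulation honours noise, bias, and detection", {
  d <- make_design(seed = 7)
  tr <- simulate_gene_truth(30, noise_cv = 0, detect_prob = 1, seed = 7)
  pg <- simulate_protein_ibaq(tr, d, seed = 7)
  pm <- protein_matrix(pg)
  latent <- truth_matrix(tr, d) * 2^tr$protein_bias_log2 * 1e9
  expect_equal(unname(pm$ibaq), unname(latent), tolerance = 1e-12)

  tr$detect_prob <- 0
  pg0 <- simulate_protein_ibaq(tr, d, seed = 7)
  expect_true(all(is.na(protein_matrix(pg0)$ibaq)))

  # empirical log-noise sd matches the requested CV's lognormal sigma
  tr2 <- simulate_gene_truth(500, noise_cv = 0.3, seed = 8)
  pm2 <- protein_matrix(simulate_protein_ibaq(tr2, d, seed = 8))
  latent2 <- truth_matrix(tr2, d) * 2^tr2$protein_bias_log2 * 1e9
  sigma <- sd(log(pm2$ibaq / latent2))
  expect_equal(sigma, sqrt(log(1 + 0.3^2)), tolerance = 0.05)
})

test_that("OD curves follow the closed form and round-trip the rate", {
  od <- simulate_od_curve(0.2, od0 = 0.2, duration = 5, interval = 5,
                          noise_sd = 0)
  expect_equal(od$od[od$time == 5], 0.2 * exp(1), tolerance = 1e-12)
  expect_equal(nrow(simulate_od_curve(0.2, duration = 1)), 121)

  clean <- simulate_od_curve(0.15, duration = 1, noise_sd = 0)
  expect_equal(estimate_growth_rate(clean), 0.15, tolerance = 1e-12)
  noisy <- simulate_od_curve(0.15, duration = 1, noise_sd = 0.01, seed = 9)
  expect_equal(estimate_growth_rate(noisy), 0.15, tolerance = 0.03)
})

test_that("benchmark bundle is reproducible and internally consistent", {
  b1 <- simulate_benchmark(n_genes = 200, n_proteins = 80, seed = 5)
  b2 <- simulate_benchmark(n_genes = 200, n_proteins = 80, seed = 5)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  expect_equal(dim(b1$counts), c(200, 24))
  expect_true(all(b1$protein_ids %in% b1$truth$gene_id))
  expect_true(all(lengths(b1$gene_sets) > 0))
})
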