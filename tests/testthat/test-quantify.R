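test_that("growth-rate estimation is exact on clean exponentials", {
  t <- seq(0, 2, by = 0.1)
  expect_equal(estimate_growth_rate(t, 0.2 * exp(0.2 * t)), 0.2,
               tolerance = 1e-12)
  expect_equal(estimate_growth_rate(t, rep(0.4, length(t))), 0)
  expect_error(estimate_growth_rate(t, c(-1, rep(1, length(t) - 1))),
               "positive")
})

test_that("size factors implement median-of-ratios", {
  m <- matrix(c(10, 20, 30), 3, 4, dimnames = list(NULL, letters[1:4]))
  expect_equal(unname(size_factors(m)), rep(1, 4))

  two <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  expect_equal(unname(size_factors(two)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # invariant to a global rescaling: the geometric means rescale too
  expect_equal(unname(size_factors(two * 10)),
               unname(size_factors(two)), tolerance = 1e-12)

  holed <- rbind(c(0, 5), c(4, 0))
  expect_error(size_factors(holed), "nonzero")
})

test_that("size factors recover planted library-scale ratios", {
  d <- make_design(seed = 1)
  tr <- simulate_gene_truth(400, seed = 1)
  lib <- 1e6 * exp(seq(-0.3, 0.3, length.out = 24))
  cnt <- simulate_rna_counts(tr, d, library_size = lib, seed = 1)
  sf <- size_factors(cnt)
  expect_equal(unname(sf / exp(mean(log(sf)))),
               unname(lib / exp(mean(log(lib)))), tolerance = 0.02)
})

test_that("normalisation and fraction conversions conserve mass", {
  cnt <- matrix(c(10, 0, 6), 3, 1)
  expect_equal(unname(normalize_counts(cnt, 2)[, 1]), c(5, 0, 3))

  phi <- mass_fractions(matrix(c(3, 1), 2, 1), masses = c(10, 20))
  expect_equal(unname(phi[, 1]), c(0.6, 0.4))
  expect_equal(unname(mass_fractions(matrix(5, 1, 1), 7)[, 1]), 1)

  set.seed(2)
  ib <- matrix(rlnorm(60), 10, 6)
  mass <- runif(10, 10, 100)
  expect_equal(unname(colSums(mass_fractions(ib, mass))), rep(1, 6),
               tolerance = 1e-9)
  psi <- number_fractions_protein(ib)
  expect_equal(unname(colSums(psi)), rep(1, 6), tolerance = 1e-9)
  # number fractions ignore masses entirely
  expect_equal(psi, number_fractions_protein(ib), tolerance = 1e-12)

  lens <- runif(10, 500, 3000)
  psim <- number_fractions_rna(ib, lens)
  expect_equal(unname(colSums(psim)), rep(1, 6), tolerance = 1e-9)
  # equal counts and equal lengths spread mass evenly
  even <- number_fractions_rna(matrix(4, 5, 2), rep(1000, 5))
  expect_true(all(abs(even - 0.2) < 1e-12))
  # doubling one gene's length halves its share before renormalisation
  l2 <- lens; l2[1] <- 2 * lens[1]
  expect_lt(number_fractions_rna(ib, l2)[1, 1], psim[1, 1])
})

test_that("detection filters drop the right rows", {
  d <- simulate_design(2, 3, 0.1, 0.2, 0, seed = 1)
  m <- matrix(1, 4, 6, dimnames = list(paste0("g", 1:4), d$sample_id))
  m[2, 4] <- NA                       # missing in one replicate of cond02
  m[3, 4:6] <- NA                     # fully absent from cond02
  m[4, c(1, 4)] <- NA                 # one replicate missing everywhere

  expect_equal(rownames(filter_detected(m, "all_samples")), "g1")
  expect_equal(attr(filter_detected(m, "all_samples"), "removed"),
               c("g2", "g3", "g4"))
  # complete in at least one condition keeps g2 (cond01 full) and g3,
  # drops g4 (no condition fully observed)
  percond <- filter_detected(m, "all_replicates_within_any_condition", d)
  expect_setequal(rownames(percond), c("g1", "g2", "g3"))
  expect_equal(nrow(filter_detected(m, "at_least_one")), 4)
})

test_that("z-scores standardise rows and are affine-invariant", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1, 3))
  expect_equal(unname(z[1, ]), c(-1, 0, 1))
  set.seed(3)
  m <- matrix(rnorm(50), 5, 10)
  z <- zscore_rows(m)
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-9)
  expect_equal(zscore_rows(3 * m + 7), z, tolerance = 1e-9)
  expect_error(zscore_rows(matrix(1, 2, 3)), "constant")
  expect_warning(zk <- zscore_rows(rbind(m, 0), drop_constant = TRUE),
                 "dropped")
  expect_equal(nrow(zk), 5)
})
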