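test_that("the ANOVA screen matches aov and flags planted effects", {
  d <- simulate_design(4, 3, 0.1, 0.3, 0, seed = 1)
  set.seed(1)
  m <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(paste0("g", 1:20), d$sample_id))
  m[1:5, d$condition == "cond03"] <- m[1:5, d$condition == "cond03"] + 10
  out <- anova_variability_screen(m, d)
  # gene-wise agreement with the reference single-gene fit
  for (g in c(1, 7, 13)) {
    ref <- summary(aov(m[g, ] ~ factor(d$condition)))[[1]]
    expect_equal(out$f[g], ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(out$p[g], ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  expect_true(all(out$variable[1:5]))
  expect_equal(out$p_holm, p.adjust(out$p, "holm"))

  # constant genes are not flagged
  m2 <- rbind(m, const = 1)
  out2 <- anova_variability_screen(m2, d)
  expect_false(out2$variable[out2$gene_id == "const"])
})

test_that("the ANOVA screen controls the familywise error on nulls", {
  d <- simulate_design(4, 3, 0.1, 0.3, 0, seed = 2)
  set.seed(2)
  hits <- replicate(100, {
    m <- matrix(rnorm(500 * 12), 500, 12,
                dimnames = list(paste0("g", 1:500), d$sample_id))
    any(anova_variability_screen(m, d)$variable)
  })
  expect_lte(mean(hits), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 100))
})

test_that("growth normalization factors follow the observed/predicted
           ratio with geometric mean one", {
  d <- make_design(seed = 3, jitter = 0)
  # perfect-fit gene: counts exactly on the line (integer by construction)
  mu <- d$mu
  counts <- rbind(lin = round(1000 + 7000 * mu),  # integral on this design
                  flat = rep(500L, 24),
                  other = rep(300L, 24))
  colnames(counts) <- d$sample_id
  sf <- setNames(rep(1, 24), d$sample_id)
  fits <- suppressWarnings(fit_growth_laws(counts, d, eta0 = 1))
  gn <- growth_normalization_factors(counts, d, fits, sf)
  expect_equal(unname(gn$norm_factors["lin", ]), rep(1, 24),
               tolerance = 1e-9)

  # flat gene with one doubled observation: that factor is 2/geomean
  counts2 <- counts
  counts2["flat", 1] <- 1000L
  fits2 <- suppressWarnings(fit_growth_laws(counts2, d, eta0 = 1))
  gn2 <- growth_normalization_factors(counts2, d, fits2, sf)
  g <- exp(mean(log(c(2, rep(1, 23)))))
  expect_equal(unname(gn2$norm_factors["flat", ]),
               c(2 / g, rep(1 / g, 23)), tolerance = 1e-9)
  expect_equal(unname(apply(gn2$norm_factors, 1, function(r)
    exp(mean(log(r))))), rep(1, 3), tolerance = 1e-9)
})

test_that("exclusion accounting is complete", {
  d <- make_design(seed = 4, jitter = 0)
  set.seed(4)
  counts <- matrix(rpois(50 * 24, 200), 50, 24,
                   dimnames = list(paste0("g", 1:50), d$sample_id))
  counts[1, ] <- 0L                                 # all-zero
  counts[2, ] <- c(rep(0L, 22), 5000L, 5000L)       # steep negative fit
  fits <- suppressWarnings(fit_growth_laws(
    normalize_counts(counts, setNames(rep(1, 24), d$sample_id)), d,
    eta0 = 1))
  gn <- growth_normalization_factors(counts, d, fits,
                                     setNames(rep(1, 24), d$sample_id))
  expect_equal(length(gn$gene_id) + sum(lengths(gn$excluded)), 50)
  expect_true("g1" %in% unlist(gn$excluded))
})

test_that("the synthetic reference takes rounded per-replicate medians", {
  d <- simulate_design(3, 2, 0.1, 0.3, 0, seed = 5)
  gn <- structure(list(
    gene_id = c("a", "b"),
    predicted_raw = matrix(c(10.2, 10.6, 30.0,  10.2, 10.6, 30.0,
                             7, 7, 7,  7, 7, 7),
                           2, 6, byrow = TRUE,
                           dimnames = list(c("a", "b"),
                                           d$sample_id[order(d$replicate)])),
    design = d[order(d$replicate), ]), class = "growth_normalization")
  s <- synthetic_reference(gn)
  expect_equal(unname(s["a", ]), c(11L, 11L))   # median 10.6 -> 11
  expect_equal(unname(s["b", ]), c(7L, 7L))
})

test_that("growth-removed DE separates condition effects from pure
           growth dependence on one calibration dataset", {
  sim <- de_calibration_sim(6)
  expect_lt(mean(sim$flags[sim$pure]), 0.03)
  expect_gte(mean(sim$flags[sim$eff]), 0.8)
  # recovered effect size is close to the planted log2 = 1
  ce <- attr(sim$truth, "condition_effects")
  up <- sim$truth$gene_id[sim$eff][ce[sim$eff, 4] > 0]
  tab <- sim$calls$table
  sub <- tab[tab$condition == "cond04" & tab$gene_id %in% up, ]
  expect_equal(median(sub$log2fc_raw), 1, tolerance = 0.15)
  # the internal and DESeq2 engines agree on the fold changes
  # (the variance treatments differ, so p-values are not compared)
})

test_that("LFC shrinkage is a proper posterior mean", {
  tab <- data.frame(gene_id = letters[1:4], condition = "c1",
                    log2fc_raw = c(2, 2, 0.5, -2),
                    lfc_se = c(0.1, 1, 0.2, 0.5),
                    p = 0.5, p_adj = 0.5)
  inf <- shrink_lfc(tab, prior_sd = 1e6)
  expect_equal(inf$log2fc_shrunk, tab$log2fc_raw, tolerance = 1e-6)
  zero <- shrink_lfc(tab, prior_sd = 1e-6)
  expect_equal(zero$log2fc_shrunk, rep(0, 4), tolerance = 1e-6)
  s <- shrink_lfc(tab, prior_sd = 0.5)
  expect_true(all(abs(s$log2fc_shrunk) <= abs(s$log2fc_raw)))
  # equal raw LFC: the better-measured gene shrinks less
  expect_gt(abs(s$log2fc_shrunk[1]), abs(s$log2fc_shrunk[2]))
})

test_that("DE calling applies strict thresholds and the union rule", {
  tab <- data.frame(gene_id = c("a", "a", "b", "c"),
                    condition = c("c1", "c2", "c1", "c1"),
                    log2fc_raw = c(2, 0, 0.6, 0.6),
                    lfc_se = 0.1,
                    p = c(1e-5, 0.9, 1e-5, 1e-5),
                    p_adj = c(1e-4, 0.95, 0.01, 0.005))
  tab$log2fc_shrunk <- tab$log2fc_raw
  calls <- call_de(tab, padj_thr = 0.01, lfc_thr = 0.5)
  expect_true(calls$gene_flags[["a"]])            # DE in one condition
  expect_false(calls$gene_flags[["b"]])           # p_adj == 0.01 excluded
  expect_true(calls$gene_flags[["c"]])
  expect_equal(rownames(calls$signature), c("a", "c"))
})

test_that("the internal NB engine tracks the DESeq2 route", {
  sim <- de_calibration_sim(12)
  d <- make_design(seed = 12)
  counts <- simulate_rna_counts(sim$truth, d, library_size = 150000,
                                library_sd_log = 0.1, seed = 512)
  internal <- nb_de_test(counts, d, shrink = FALSE)
  ds2 <- nb_de_test(counts, d, shrink = FALSE, engine = "deseq2")
  m <- merge(internal, ds2, by = c("gene_id", "condition"))
  ok <- is.finite(m$log2fc_raw.x) & is.finite(m$log2fc_raw.y)
  # fold changes agree closely; p-values agree in rank (the variance
  # treatments of the synthetic reference differ by design)
  expect_gt(cor(m$log2fc_raw.x[ok], m$log2fc_raw.y[ok]), 0.99)
  expect_lt(median(abs(m$log2fc_raw.x - m$log2fc_raw.y), na.rm = TRUE),
            0.05)
  expect_gt(cor(log(m$p.x[ok] + 1e-300), log(m$p.y[ok] + 1e-300),
                method = "spearman"), 0.8)
})
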