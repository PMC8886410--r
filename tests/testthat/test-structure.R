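test_that("clustering splits separated blobs and handles duplicates", {
  set.seed(1)
  z <- rbind(matrix(rnorm(100, 0), 10, 10),
             matrix(rnorm(100, 10), 10, 10))
  rownames(z) <- paste0("g", 1:20)
  cl <- hierarchical_clusters(z, 2)
  expect_equal(length(unique(cl$labels[1:10])), 1)
  expect_equal(length(unique(cl$labels[11:20])), 1)
  expect_false(cl$labels[1] == cl$labels[11])

  dup <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  tr <- hierarchical_clusters(dup, 2)$tree
  expect_equal(min(tr$height), 0)
  expect_true(all(diff(tr$height) >= 0))
  expect_error(hierarchical_clusters(dup, 5), "between 2")
})

test_that("ward.D2 merge heights match the closed form on three points", {
  # 1-d points 0, 1, 5: first merge at euclidean distance 1; second at
  # the Ward.D2 cost sqrt((2*1*(4.5)^2 + ... )) given by Lance-Williams
  z <- matrix(c(0, 1, 5), 3, 1)
  h <- hierarchical_clusters(cbind(z, 0), 2)$tree$height
  expect_equal(h[1], 1)
  # merging {0,1} with {5}: d^2 = (2*25 + 2*16 - 1)/3
  expect_equal(h[2], sqrt((2 * 25 + 2 * 16 - 1) / 3))
})

test_that("clustering is invariant to row permutation up to labels", {
  set.seed(2)
  z <- matrix(rnorm(300), 30, 10,
              dimnames = list(paste0("g", 1:30), NULL))
  perm <- sample(30)
  c1 <- hierarchical_clusters(z, 4)$labels
  c2 <- hierarchical_clusters(z[perm, ], 4)$labels[rownames(z)]
  expect_equal(length(unique(paste(c1, c2))), 4)   # 1-to-1 label map
})

test_that("PCA decomposes variance and reconstructs the matrix", {
  set.seed(3)
  # rank-1 matrix: one sample pattern shared by every gene
  pat <- rnorm(8)
  z <- outer(rnorm(40), pat)
  rownames(z) <- paste0("g", 1:40)
  p <- pca_structure(z)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-9)
  expect_equal(unname(p$pc1_fraction), rep(1, 40), tolerance = 1e-9)

  # full reconstruction and the deterministic orientation
  z2 <- matrix(rnorm(200), 20, 10,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  p2 <- pca_structure(z2)
  expect_equal(p2$loadings %*% t(p2$scores), z2, tolerance = 1e-9)
  top <- apply(p2$scores, 2, function(s) s[which.max(abs(s))])
  expect_true(all(top > 0))

  # orthogonal two-block design: the bigger block owns PC1
  blockA <- outer(rnorm(30, 0, 3), c(rep(1, 5), rep(0, 5)))
  blockB <- outer(rnorm(10, 0, 1), c(rep(0, 5), rep(1, 5)))
  zb <- rbind(blockA, blockB)
  pb <- pca_structure(zb)
  expect_gt(min(pb$pc1_fraction[1:30]), 0.9)
  expect_lt(max(pb$pc1_fraction[31:40]), 0.1)
})

test_that("WFSP labels track the dominant expression mode", {
  set.seed(4)
  pat <- c(rep(1, 4), rep(-1, 4))            # bimodal condition split
  signs <- rep(c(1, -1), each = 20)
  z <- outer(signs * runif(40, 0.5, 2), pat) +
    matrix(rnorm(320, 0, 0.05), 40, 8)
  noise <- matrix(rnorm(160, 0, 1), 20, 8)
  zz <- rbind(z, noise)
  rownames(zz) <- paste0("g", 1:60)
  p <- pca_structure(zz)
  w <- wfsp_classify(p, zz)
  expect_true(all(w[1:20] == w[1]))          # consistent within arm
  expect_true(all(w[21:40] == w[21]))
  expect_false(w[1] == w[21])                # arms get opposite labels
  expect_gt(mean(w[41:60] == "none"), 0.8)   # noise genes unlabelled
  # sign source (loadings vs explicit correlations) agrees
  expect_equal(wfsp_classify(p), w)
})

test_that("barcode lengths measure capped deviation from the median", {
  d <- simulate_design(4, 3, 0.1, 0.3, 0, seed = 5)
  phi <- matrix(0.1, 3, 12, dimnames = list(paste0("g", 1:3), d$sample_id))
  phi[2, d$condition == "cond02"] <- 0.4          # x = 4M -> capped at 2
  phi[3, d$condition == "cond03"] <- NA           # imputed to 0 -> -1
  bc <- barcode_lengths(phi, d)
  expect_equal(unname(bc$l[1, ]), rep(0, 4))
  expect_equal(bc$l["g2", "cond02"], 2)
  expect_equal(bc$l["g3", "cond03"], -1)
  expect_true(all(bc$l >= -1 & bc$l <= 2, na.rm = TRUE))

  # replicate medians shrug off a single wild replicate
  phi2 <- phi
  phi2[1, 1] <- 50
  bc2 <- barcode_lengths(phi2, d)
  expect_equal(bc2$x["g1", "cond01"], 0.1)

  # an all-zero gene has undefined lengths
  phi3 <- rbind(phi, g4 = 0)
  bc3 <- barcode_lengths(phi3, d)
  expect_equal(bc3$undefined, "g4")
  expect_true(all(is.na(bc3$l["g4", ])))
})
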