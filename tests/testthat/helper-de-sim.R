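de_calibration_sim <- function(seed) {
  # one calibration dataset: 200 pure growth-law genes (R/P, no condition
  # effect) plus 100 genes with balanced +/-1 log2 effects in one
  # condition, mean 500 counts, NB dispersion 0.05
  d <- make_design(seed = seed)
  n_pure <- 200; n_eff <- 100; n <- n_pure + n_eff
  truth <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    sector_true = factor(c(rep(c("R", "P"), n_pure / 2), rep("Q", n_eff)),
                         c("R", "P", "Q")),
    slope_true = 0, intercept_true = 1 / n, fc_true = 0,
    dispersion = 0.05, noise_cv = 0.3, length = 1500, mass = 50,
    detect_prob = 1, protein_bias_log2 = 0, stringsAsFactors = FALSE)
  set.seed(seed)
  rp <- truth$sector_true != "Q"
  truth$fc_true[rp] <- runif(n_pure, 0.75, 2) *
    ifelse(truth$sector_true[rp] == "R", 1, -1)
  truth$slope_true <- truth$fc_true * (1 / n) / 0.3
  truth$intercept_true <- (1 / n) * (1 - truth$fc_true / 2)
  ce <- matrix(0, n, 8, dimnames = list(truth$gene_id,
                                        sprintf("cond%02d", 1:8)))
  ce[(n_pure + 1):n, 4] <- rep(c(1, -1), n_eff / 2)
  attr(truth, "condition_effects") <- ce
  counts <- simulate_rna_counts(truth, d, library_size = 500 * n,
                                library_sd_log = 0.1, seed = seed + 500)
  calls <- call_de(nb_de_test(counts, d))
  flags <- calls$gene_flags[truth$gene_id]
  flags[is.na(flags)] <- FALSE
  list(truth = truth, calls = calls, flags = flags,
       pure = 1:n_pure, eff = (n_pure + 1):n)
}
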