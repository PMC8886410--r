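# Independent brute-force oracles used across the suite.

# Repeated median by double enumeration: per-point medians of pairwise
# slopes/intercepts, then the median over points.
brute_rmlm <- function(x, y) {
  n <- length(x)
  ms <- mt <- numeric(n)
  for (i in seq_len(n)) {
    s <- t <- c()
    for (j in seq_len(n)) {
      if (j == i || abs(x[j] - x[i]) < 1e-12) next
      s <- c(s, (y[j] - y[i]) / (x[j] - x[i]))
      t <- c(t, (x[j] * y[i] - x[i] * y[j]) / (x[j] - x[i]))
    }
    ms[i] <- median(s); mt[i] <- median(t)
  }
  c(slope = median(ms), intercept = median(mt))
}

# Hypergeometric upper tail by explicit summation of the pmf.
brute_hyper_tail <- function(k, set_size, universe, query) {
  xs <- k:min(set_size, query)
  sum(choose(set_size, xs) * choose(universe - set_size, query - xs)) /
    choose(universe, query)
}

# GSEA enrichment score by an explicit step-by-step running sum.
brute_gsea_es <- function(stats_sorted, member, weight_exponent = 1) {
  n <- length(stats_sorted)
  w <- abs(stats_sorted)^weight_exponent
  nr <- sum(w[member])
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- if (member[i]) run + w[i] / nr else run - 1 / (n - sum(member))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# A 24-sample design matching the default study shape.
make_design <- function(seed = 1, jitter = 0.02)
  simulate_design(8, 3, 0.05, 0.28, jitter, seed = seed)

# Noiseless expression matrix straight from planted lines (with condition
# effects), bypassing the count layer.
truth_matrix <- function(truth, design) {
  ce <- attr(truth, "condition_effects")
  m <- outer(truth$slope_true, design$mu) + truth$intercept_true
  m <- m * 2^ce[, match(design$condition, colnames(ce)), drop = FALSE]
  dimnames(m) <- list(truth$gene_id, design$sample_id)
  m
}
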