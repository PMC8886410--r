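#' Simulate a multi-condition steady-state culture design
#'
#' Emulates a study in which cultures are grown in continuous culture under
#' several media (conditions), each in biological replicates, and the
#' steady-state growth rate of every culture is measured. Condition-level
#' mean growth rates are spread evenly over `[mu_low, mu_high]`; each
#' replicate's rate is the condition mean times a lognormal jitter
#' `exp(N(0, replicate_jitter))`.
#'
#' @param n_conditions number of conditions (>= 2).
#' @param n_replicates biological replicates per condition.
#' @param mu_low,mu_high range of condition mean growth rates, per hour.
#' @param replicate_jitter lognormal sd of replicate-level growth-rate
#'   variation (0 for identical replicates).
#' @param seed optional integer seed; fixed seed gives identical output.
#' @return a data frame (the sample design) with columns `sample_id`,
#'   `condition`, `replicate`, `mu`.
#' @examples
#' design <- simulate_design(8, 3, 0.05, 0.28, 0.02, seed = 1)
#' @export
simulate_design <- function(n_conditions = 8, n_replicates = 3,
                            mu_low = 0.05, mu_high = 0.28,
                            replicate_jitter = 0.02, seed = NULL) {
  stopifnot(n_conditions >= 2, n_replicates >= 1, replicate_jitter >= 0)
  if (!(mu_low > 0 && mu_high > mu_low))
    stop("growth rates must satisfy 0 < mu_low < mu_high")
  if (!is.null(seed)) set.seed(seed)
  cond_mu <- seq(mu_low, mu_high, length.out = n_conditions)
  cond <- sprintf("cond%02d", seq_len(n_conditions))
  design <- expand.grid(replicate = seq_len(n_replicates),
                        condition = cond, stringsAsFactors = FALSE)
  design <- design[, c("condition", "replicate")]
  design$mu <- rep(cond_mu, each = n_replicates) *
    exp(stats::rnorm(nrow(design), 0, replicate_jitter))
  design$sample_id <- paste0(design$condition, "_r", design$replicate)
  rownames(design) <- NULL
  design[, c("sample_id", "condition", "replicate", "mu")]
}

#' Simulate ground-truth gene parameters for a growth-law benchmark
#'
#' Draws per-gene generative parameters for the two regulatory layers the
#' analysis is meant to separate: a linear growth-rate dependence (R, P or Q
#' sector) and condition-specific log2 offsets. Each R/P gene is given a
#' target fold-change statistic FC and a midpoint relative abundance `m`
#' (lognormal, normalised to sum to 1 over genes); its line is then
#' `slope = FC * m / mu_max`, `intercept = m * (1 - FC / 2)`, so that the
#' growth-law FC of the planted line equals the target exactly. Q genes have
#' slope 0. A fraction of genes additionally receives condition-specific
#' offsets; half of those follow a shared bimodal split of the conditions
#' (one set of media up, the rest down, emulating a nutrient-specific
#' expression mode that is orthogonal to growth rate), the other half get an
#' offset in a single random condition.
#'
#' @param n_genes number of genes.
#' @param sector_props proportions of R, P, Q genes (must sum to 1); counts
#'   are deterministic (largest-remainder rounding) unless
#'   `assignment = "multinomial"`.
#' @param fc_range range of |FC| for R and P genes (|FC| <= 2 keeps planted
#'   abundances positive over the growth-rate range).
#' @param mu_max growth-rate range end defining the FC statistic, per hour.
#' @param condition_effect_frac fraction of genes with condition-specific
#'   offsets.
#' @param condition_effect_size range of |log2 offset| for affected genes.
#' @param n_conditions number of conditions the offsets are drawn for.
#' @param dispersion negative-binomial dispersion of the RNA counts
#'   (var = m + dispersion * m^2); 0 means noiseless counts.
#' @param noise_cv lognormal coefficient of variation of protein
#'   intensities; 0 means noiseless.
#' @param detect_prob per-observation protein detection probability.
#' @param protein_bias_sd_log2 sd of the per-gene log2 protein-to-mRNA
#'   amplification offset (stable across samples); it sets the latent
#'   gene-wise protein-mRNA correlation (about 0.8 at the default 1.3
#'   with the default abundance spread).
#' @param assignment `"deterministic"` (exact sector counts) or
#'   `"multinomial"`.
#' @param seed optional integer seed.
#' @return a data frame with one row per gene: `gene_id`, `sector_true`,
#'   `slope_true`, `intercept_true`, `fc_true`, `dispersion`, `noise_cv`,
#'   `length`, `mass`, `detect_prob`, and a `condition_effects` attribute
#'   (genes x conditions matrix of log2 offsets).
#' @export
simulate_gene_truth <- function(n_genes,
                                sector_props = c(R = 0.3, P = 0.25, Q = 0.45),
                                fc_range = c(0.75, 2), mu_max = 0.3,
                                condition_effect_frac = 0.2,
                                condition_effect_size = c(0.5, 2),
                                n_conditions = 8,
                                dispersion = 0.02, noise_cv = 0.3,
                                detect_prob = 1, protein_bias_sd_log2 = 1.3,
                                assignment = c("deterministic", "multinomial"),
                                seed = NULL) {
  assignment <- match.arg(assignment)
  if (abs(sum(sector_props) - 1) > 1e-9)
    stop("sector_props must sum to 1")
  stopifnot(n_genes >= 1, fc_range[1] > 0, fc_range[2] <= 2, mu_max > 0)
  if (!is.null(seed)) set.seed(seed)
  sectors <- c("R", "P", "Q")
  props <- sector_props[sectors]
  if (assignment == "deterministic") {
    counts <- floor(n_genes * props)
    rem <- n_genes - sum(counts)
    if (rem > 0) {
      extra <- order(n_genes * props - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    sector <- sample(rep(sectors, counts))
  } else {
    sector <- sample(sectors, n_genes, replace = TRUE, prob = props)
  }
  sector <- factor(sector, levels = sectors)
  m <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
  m <- m / sum(m)
  fc <- numeric(n_genes)
  rp <- sector != "Q"
  fc[rp] <- stats::runif(sum(rp), fc_range[1], fc_range[2]) *
    ifelse(sector[rp] == "R", 1, -1)
  slope <- fc * m / mu_max
  intercept <- m * (1 - fc / 2)
  ce <- matrix(0, n_genes, n_conditions,
               dimnames = list(NULL, sprintf("cond%02d", seq_len(n_conditions))))
  n_eff <- round(condition_effect_frac * n_genes)
  if (n_eff > 0) {
    hit <- sample.int(n_genes, n_eff)
    split_conditions <- sample.int(n_conditions, floor(n_conditions / 2))
    bimodal <- seq_len(n_eff) <= ceiling(n_eff / 2)
    for (k in seq_len(n_eff)) {
      g <- hit[k]
      delta <- stats::runif(1, condition_effect_size[1],
                            condition_effect_size[2]) * sample(c(-1, 1), 1)
      if (bimodal[k]) ce[g, split_conditions] <- delta
      else ce[g, sample.int(n_conditions, 1)] <- delta
    }
  }
  truth <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n_genes)),
    sector_true = sector, slope_true = slope, intercept_true = intercept,
    fc_true = fc, dispersion = dispersion, noise_cv = noise_cv,
    length = round(stats::rlnorm(n_genes, log(1500), 0.5)),
    mass = stats::rlnorm(n_genes, log(50), 0.5),
    detect_prob = detect_prob,
    protein_bias_log2 = stats::rnorm(n_genes, 0, protein_bias_sd_log2),
    stringsAsFactors = FALSE)
  rownames(ce) <- truth$gene_id
  attr(truth, "condition_effects") <- ce
  attr(truth, "mu_max") <- mu_max
  truth
}

## Planted relative abundance of every gene in every sample:
## (intercept + slope * mu) * 2^condition_effect, clamped at `floor`.
latent_abundance <- function(truth, design, floor = 1e-10) {
  ce <- attr(truth, "condition_effects")
  rel <- outer(truth$slope_true, design$mu) + truth$intercept_true
  if (!is.null(ce)) {
    cond_idx <- match(design$condition, colnames(ce))
    if (anyNA(cond_idx))
      stop("design conditions not covered by the truth's condition effects")
    rel <- rel * 2^ce[, cond_idx, drop = FALSE]
  }
  if (any(rel < floor)) {
    warning(sum(rel < floor), " planted abundances clamped at the floor")
    rel[rel < floor] <- floor
  }
  dimnames(rel) <- list(truth$gene_id, design$sample_id)
  rel
}

#' Simulate an RNA-seq raw count matrix
#'
#' Counts are negative-binomial around `library_size * abundance * length
#' bias`: the abundance is the planted relative (molecule) abundance of the
#' gene in that sample (growth-law line times condition effect; see
#' [simulate_gene_truth()]), and reads scale with transcript length, so the
#' mean carries a `length / nominal_length` factor that the number-fraction
#' conversion downstream removes again. The NB variance is
#' `m + dispersion * m^2`. A per-gene `dispersion` of 0 is the exact
#' noiseless limit: counts equal the rounded means.
#'
#' @param truth output of [simulate_gene_truth()].
#' @param design output of [simulate_design()].
#' @param library_size scalar or per-sample vector of expected library
#'   sizes (total counts).
#' @param library_sd_log lognormal sd of per-sample library-size jitter,
#'   applied when `library_size` is a scalar.
#' @param abundance_floor clamp for negative planted means (warned about).
#' @param nominal_length reference transcript length (nt) scaling the
#'   length bias.
#' @param seed optional integer seed.
#' @return integer matrix of raw counts, genes x samples.
#' @export
simulate_rna_counts <- function(truth, design, library_size = 2e6,
                                library_sd_log = 0.15,
                                abundance_floor = 1e-10,
                                nominal_length = 1500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(design)
  lib <- if (length(library_size) == 1L) {
    library_size * exp(stats::rnorm(ns, 0, library_sd_log))
  } else {
    stopifnot(length(library_size) == ns)
    library_size
  }
  rel <- latent_abundance(truth, design, floor = abundance_floor)
  rel <- rel * (truth$length / nominal_length)
  mu <- sweep(rel, 2, lib, `*`)
  d <- truth$dispersion
  counts <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  noiseless <- d == 0
  if (any(noiseless))
    counts[noiseless, ] <- round(mu[noiseless, , drop = FALSE])
  if (any(!noiseless)) {
    i <- which(!noiseless)
    counts[i, ] <- stats::rnbinom(length(i) * ncol(mu),
                                  mu = mu[i, ], size = rep(1 / d[i], ncol(mu)))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a label-free proteomics protein-group table
#'
#' iBAQ intensities are the planted relative abundances times the gene's
#' fixed protein-to-mRNA amplification offset (`2^protein_bias_log2`),
#' scaled to an intensity unit, with multiplicative lognormal noise of
#' coefficient of variation `noise_cv` and Bernoulli(`detect_prob`)
#' per-observation detection; undetected observations are `NA`. The output mimics a
#' MaxQuant proteinGroups table: columns `Protein IDs`,
#' `Mol. weight [kDa]`, and one `iBAQ <sample_id>` column per sample.
#'
#' @inheritParams simulate_rna_counts
#' @param intensity_scale multiplier from relative abundance to intensity.
#' @return a data frame in proteinGroups-like layout.
#' @export
simulate_protein_ibaq <- function(truth, design, intensity_scale = 1e9,
                                  abundance_floor = 1e-10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rel <- latent_abundance(truth, design, floor = abundance_floor)
  bias <- if (is.null(truth$protein_bias_log2)) 1 else
    2^truth$protein_bias_log2
  latent <- rel * bias * intensity_scale
  sigma <- sqrt(log(1 + truth$noise_cv^2))   # lognormal sd from CV
  noise <- matrix(stats::rnorm(length(latent)), nrow(latent))
  intensity <- latent * exp(noise * sigma)
  detected <- matrix(stats::runif(length(latent)), nrow(latent)) <=
    truth$detect_prob
  intensity[!detected] <- NA_real_
  out <- data.frame(truth$gene_id, truth$mass, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("Protein IDs", "Mol. weight [kDa]")
  ib <- as.data.frame(intensity)
  names(ib) <- paste("iBAQ", design$sample_id)
  cbind(out, ib)
}

#' Simulate an optical-density regrowth curve
#'
#' Exponential growth `od0 * exp(mu * t)` sampled every `interval` hours
#' with multiplicative lognormal noise, emulating the regrowth phase used to
#' measure a culture's growth rate after a twofold dilution.
#'
#' @param mu growth rate, per hour (> 0).
#' @param od0 starting optical density (> 0).
#' @param duration total time, hours.
#' @param interval sampling interval, hours (default 30 s).
#' @param noise_sd sd of the lognormal measurement noise.
#' @param seed optional integer seed.
#' @return a data frame with columns `time` (h) and `od`.
#' @export
simulate_od_curve <- function(mu, od0 = 0.2, duration = 1,
                              interval = 30 / 3600, noise_sd = 0,
                              seed = NULL) {
  stopifnot(mu > 0, od0 > 0, duration > 0, interval > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = interval)
  od <- od0 * exp(mu * t) * exp(stats::rnorm(length(t), 0, noise_sd))
  data.frame(time = t, od = od)
}

#' Simulate the full synthetic benchmark
#'
#' Generates the complete input bundle the analysis pipeline consumes:
#' a sample design, ground-truth gene parameters, an RNA-seq count matrix
#' for all genes, a proteomics table for a subset of genes, and a small
#' gene-set collection built from the planted structure (sector and
#' condition-responsive sets plus random sets) for the enrichment stage.
#' A single `seed` expands into fixed per-stage child seeds
#' (`seed * 1000 + stage offset`), so partial reruns of a stage are
#' reproducible on their own.
#'
#' @param n_genes number of RNA genes.
#' @param n_proteins number of genes also quantified at the protein level
#'   (sampled at random from the genes).
#' @param n_conditions,n_replicates design shape.
#' @param seed integer seed driving all stages.
#' @param ... further arguments passed to [simulate_gene_truth()].
#' @return a list with `design`, `truth`, `counts`, `protein_groups`,
#'   `protein_ids`, `gene_sets`, and the `seed`.
#' @export
simulate_benchmark <- function(n_genes = 5000, n_proteins = 2000,
                               n_conditions = 8, n_replicates = 3,
                               seed = 1, ...) {
  child <- function(k) (seed * 1000 + k) %% .Machine$integer.max
  design <- simulate_design(n_conditions, n_replicates, seed = child(1))
  truth <- simulate_gene_truth(n_genes, n_conditions = n_conditions,
                               seed = child(2), ...)
  counts <- simulate_rna_counts(truth, design, seed = child(3))
  set.seed(child(4))
  protein_ids <- sort(sample(truth$gene_id, min(n_proteins, n_genes)))
  ptruth <- truth[match(protein_ids, truth$gene_id), ]
  attr(ptruth, "condition_effects") <-
    attr(truth, "condition_effects")[protein_ids, , drop = FALSE]
  pg <- simulate_protein_ibaq(ptruth, design, seed = child(5))
  gene_sets <- benchmark_gene_sets(truth, seed = child(6))
  list(design = design, truth = truth, counts = counts,
       protein_groups = pg, protein_ids = protein_ids,
       gene_sets = gene_sets, seed = seed)
}

#' Gene sets carved out of the planted benchmark structure
#'
#' Builds a small collection for exercising the enrichment stage: one set
#' per planted sector (sampled members), one set of condition-responsive
#' genes, and random background sets.
#'
#' @param truth output of [simulate_gene_truth()].
#' @param set_size members per set.
#' @param n_random number of random sets.
#' @param seed optional integer seed.
#' @return a named list of gene-id vectors.
#' @export
benchmark_gene_sets <- function(truth, set_size = 50, n_random = 5,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ce <- attr(truth, "condition_effects")
  responsive <- truth$gene_id[rowSums(abs(ce)) > 0]
  pick <- function(pool) sample(pool, min(set_size, length(pool)))
  sets <- list(
    R_sector = pick(truth$gene_id[truth$sector_true == "R"]),
    P_sector = pick(truth$gene_id[truth$sector_true == "P"]),
    Q_sector = pick(truth$gene_id[truth$sector_true == "Q"]),
    condition_responsive = pick(responsive))
  for (k in seq_len(n_random))
    sets[[paste0("random", k)]] <- pick(truth$gene_id)
  sets
}
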