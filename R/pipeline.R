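#' Run the full growth-law analysis
#'
#' End-to-end orchestration of the analysis stages on a count matrix (and
#' optionally a proteomics table): normalisation, per-gene growth-law
#' fitting, sector assignment, clustering/PCA structure, cross-omics
#' reliability and correlation report, growth-rate-removed differential
#' expression, and functional enrichment. Every stage records gene counts
#' in and out in the manifest; a fixed `seed` makes the whole run
#' reproducible (stage child seeds are `seed * 1000 + stage offset`).
#'
#' @param counts raw count matrix, genes x samples (or a benchmark bundle
#'   from [simulate_benchmark()], in which case the other inputs are taken
#'   from it).
#' @param design sample design (`sample_id`, `condition`, `replicate`,
#'   `mu`).
#' @param protein_groups optional proteinGroups-like data frame (or the
#'   list form of [read_protein_groups()]).
#' @param gene_lengths optional named per-gene transcript lengths (nt) for
#'   mRNA number fractions; equal lengths are assumed when absent.
#' @param gene_sets optional named list of gene sets for the enrichment
#'   stage.
#' @param mu_max growth-rate range end for the FC statistic, per hour.
#' @param sector_fdr tail-based fdr threshold for R/P sector membership.
#' @param de_padj,de_lfc DE thresholds (BH-adjusted p, |log2 FC|).
#' @param enrich_lfdr local-fdr significance threshold for Fisher
#'   enrichment.
#' @param n_clusters clusters for the z-score expression matrix.
#' @param n_signature_clusters clusters for the DE signature matrix (used
#'   when at least that many genes are DE).
#' @param gsea_perm permutations for preranked GSEA.
#' @param seed integer seed for all stochastic stages.
#' @param out_dir optional directory; when given, the main result tables
#'   are written there as TSV.
#' @return a list of class `"growth_analysis"` with elements
#'   `size_factors`, `normalized`, `fits`, `sector_summary`, `clusters`,
#'   `pca`, `wfsp`, `crossomics` (NULL without proteomics), `anova`,
#'   `de`, `de_calls`, `signature_clusters`, `enrichment`, `gsea`,
#'   `manifest`.
#' @export
run_growth_analysis <- function(counts, design = NULL,
                                protein_groups = NULL, gene_lengths = NULL,
                                gene_sets = NULL, mu_max = 0.3,
                                sector_fdr = 0.1, de_padj = 0.01,
                                de_lfc = 0.5, enrich_lfdr = 0.05,
                                n_clusters = 10, n_signature_clusters = 10,
                                gsea_perm = 500, seed = 1, out_dir = NULL) {
  if (is.list(counts) && !is.data.frame(counts) &&
      all(c("counts", "design") %in% names(counts))) {
    bench <- counts
    design <- bench$design
    protein_groups <- bench$protein_groups
    gene_sets <- bench$gene_sets
    gene_lengths <- stats::setNames(bench$truth$length,
                                    bench$truth$gene_id)
    counts <- bench$counts
  }
  if (is.null(design)) stop("a sample design is required")
  child <- function(k) as.integer((seed * 1000 + k) %% .Machine$integer.max)
  manifest <- list(seed = seed,
                   package = as.character(utils::packageVersion("growthlaw")),
                   stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  ## 1. normalisation
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  log_stage("normalize", genes = nrow(counts), samples = ncol(counts))

  ## 2. growth-law fits; 3. sector assignment
  fits <- fit_growth_laws(norm, design, mu_max = mu_max,
                          fdr_threshold = sector_fdr)
  sector_summary <- as.data.frame(table(sector = fits$sector))
  log_stage("fit_growth_laws", genes = nrow(fits))
  log_stage("assign_sectors",
            R = sum(fits$sector == "R"), P = sum(fits$sector == "P"),
            Q = sum(fits$sector == "Q"))

  ## 4. unsupervised structure on fully detected genes
  full <- filter_detected(norm, "all_samples")
  z <- zscore_rows(full, drop_constant = TRUE)
  clusters <- hierarchical_clusters(z, k = min(n_clusters, nrow(z)))
  pca <- pca_structure(z)
  wfsp <- wfsp_classify(pca)
  log_stage("structure", genes = nrow(z), clusters = clusters$k,
            pc1_var = pca$var_explained[1L])

  ## 5. cross-omics report (when proteomics provided)
  crossomics <- NULL
  if (!is.null(protein_groups)) {
    pm <- if (is.data.frame(protein_groups)) protein_matrix(protein_groups)
          else protein_groups
    phi <- mass_fractions(pm$ibaq, pm$masses)
    psi_p <- number_fractions_protein(pm$ibaq)
    lens <- if (is.null(gene_lengths)) rep(1, nrow(norm)) else
      gene_lengths[rownames(norm)]
    psi_m <- number_fractions_rna(norm, lens)
    report <- reliability_report(psi_p, psi_m, design)
    rr <- residual_ratio(psi_p, psi_m)
    barcode <- barcode_lengths(phi, design)
    crossomics <- list(mass_fractions = phi, psi_protein = psi_p,
                       psi_mrna = psi_m, report = report,
                       residual_ratio = rr, barcode = barcode)
    log_stage("crossomics", proteins = nrow(phi),
              mean_R = mean(report$R))
  } else {
    log_stage("crossomics", skipped = "no proteomics input; RNA-only run")
  }

  ## 6. growth-rate-removed differential expression
  anova <- anova_variability_screen(norm, design)
  de <- nb_de_test(counts, design, fits = fits)
  de_calls <- call_de(de, padj_thr = de_padj, lfc_thr = de_lfc)
  gnx <- attr(de, "growth_normalization")
  signature_clusters <- NULL
  if (sum(de_calls$gene_flags) >= max(2, n_signature_clusters)) {
    sig <- de_calls$signature
    sig[is.na(sig)] <- 0
    signature_clusters <- hierarchical_clusters(
      sig, k = min(n_signature_clusters, nrow(sig)))
  }
  log_stage("growth_removed_de",
            tested = length(gnx$gene_id),
            excluded = sum(lengths(gnx$excluded)),
            de_genes = sum(de_calls$gene_flags),
            variable_genes = sum(anova$variable))

  ## 7. enrichment
  enrichment <- gsea <- NULL
  if (!is.null(gene_sets)) {
    universe <- unique(de$gene_id)
    query <- names(de_calls$gene_flags)[de_calls$gene_flags]
    enrichment <- fisher_enrichment(query, gene_sets, universe,
                                    lfdr_threshold = enrich_lfdr)
    rs <- rank_statistic(fits)
    rs <- rs[is.finite(rs)]
    gsea <- preranked_gsea(rs, gene_sets, n_perm = gsea_perm,
                           seed = child(7))
    log_stage("enrichment", sets = length(gene_sets),
              significant = sum(enrichment$significant))
  } else {
    log_stage("enrichment", skipped = "no gene sets provided")
  }

  res <- structure(list(size_factors = sf, normalized = norm, fits = fits,
                        sector_summary = sector_summary,
                        clusters = clusters, pca = pca, wfsp = wfsp,
                        crossomics = crossomics, anova = anova, de = de,
                        de_calls = de_calls,
                        signature_clusters = signature_clusters,
                        enrichment = enrichment, gsea = gsea,
                        manifest = manifest),
                   class = "growth_analysis")
  if (!is.null(out_dir)) write_growth_analysis(res, out_dir)
  res
}

#' @export
print.growth_analysis <- function(x, ...) {
  cat("Growth-law analysis of", nrow(x$fits), "genes,",
      length(x$size_factors), "samples\n")
  cat("Stages run:", paste(names(x$manifest$stages), collapse = ", "),
      "\n")
  tab <- table(x$fits$sector)
  cat("Sectors: R =", tab[["R"]], " P =", tab[["P"]],
      " Q =", tab[["Q"]], "\n")
  cat("DE genes:", sum(x$de_calls$gene_flags), "at p_adj <",
      x$de_calls$thresholds[["padj"]], "\n")
  if (!is.null(x$crossomics))
    cat("Mean corrected protein-mRNA correlation:",
        signif(mean(x$crossomics$report$R), 3), "\n")
  invisible(x)
}

#' Write the main tables of a growth analysis as TSV
#'
#' @param res a `"growth_analysis"` object.
#' @param out_dir output directory (created if needed).
#' @export
write_growth_analysis <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(as.data.frame(res$fits), "growth_law_fits.tsv")
  w(res$anova, "anova_screen.tsv")
  w(res$de_calls$table, "de_table.tsv")
  if (!is.null(res$crossomics))
    w(res$crossomics$report, "reliability_report.tsv")
  if (!is.null(res$enrichment)) w(res$enrichment, "fisher_enrichment.tsv")
  if (!is.null(res$gsea)) w(res$gsea, "gsea.tsv")
  w(data.frame(gene_id = names(res$clusters$labels),
               cluster = res$clusters$labels), "clusters.tsv")
  manifest <- c(paste("seed:", res$manifest$seed),
                paste("package:", res$manifest$package),
                vapply(names(res$manifest$stages), function(s)
                  paste0(s, ": ",
                         paste(names(res$manifest$stages[[s]]),
                               unlist(lapply(res$manifest$stages[[s]],
                                             paste, collapse = " ")),
                               sep = "=", collapse = "; ")),
                  character(1)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
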