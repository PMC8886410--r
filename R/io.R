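#' Read a raw count matrix from TSV
#'
#' Expects a header line with `gene_id` followed by one column per sample;
#' values must be non-negative integers and gene ids unique.
#'
#' @param path TSV file path.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id")
    stop("first column of ", path, " must be 'gene_id'")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) stop("duplicated gene id(s): ",
                        paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))
    stop("non-numeric count column(s): ",
         paste(names(df)[-1L][bad], collapse = ", "))
  }
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers (check ", path, ")")
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' Read a sample sheet from TSV
#'
#' Columns `sample_id`, `condition`, `replicate`, `growth_rate` (per hour,
#' positive); (condition, replicate) pairs must be unique.
#'
#' @param path TSV file path.
#' @return sample design data frame (`sample_id`, `condition`,
#'   `replicate`, `mu`).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate", "growth_rate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample id(s) in ", path)
  if (anyDuplicated(df[c("condition", "replicate")]))
    stop("duplicated (condition, replicate) pair(s) in ", path)
  if (!is.numeric(df$growth_rate) || any(is.na(df$growth_rate)) ||
      any(df$growth_rate <= 0))
    stop("growth rates must be positive numbers")
  data.frame(sample_id = df$sample_id, condition = df$condition,
             replicate = as.integer(df$replicate), mu = df$growth_rate,
             stringsAsFactors = FALSE)
}

#' Read a protein-group quantification table from TSV
#'
#' Expects a MaxQuant-proteinGroups-like layout: columns `Protein IDs`,
#' `Mol. weight [kDa]`, and one `iBAQ <sample_id>` column per sample of
#' the design (checked when a design is given). Empty cells and zeros are
#' treated as not detected.
#'
#' @param path TSV file path.
#' @param design optional sample design whose samples must all have an
#'   iBAQ column.
#' @return a list with `ibaq` (matrix proteins x samples, NA = not
#'   detected), `masses` (named, kDa), `ids`.
#' @export
read_protein_groups <- function(path, design = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("Protein IDs", "Mol. weight [kDa]")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("protein table missing column(s): ",
                         paste(miss, collapse = ", "))
  ib_cols <- grep("^iBAQ ", names(df), value = TRUE)
  if (length(ib_cols) == 0L) stop("no 'iBAQ <sample>' columns in ", path)
  if (!is.null(design)) {
    want <- paste("iBAQ", design$sample_id)
    miss <- setdiff(want, ib_cols)
    if (length(miss)) stop("missing iBAQ column(s) for sample(s): ",
                           paste(sub("^iBAQ ", "", miss), collapse = ", "))
    ib_cols <- want
  }
  ids <- df[["Protein IDs"]]
  if (anyDuplicated(ids)) stop("duplicated protein id(s) in ", path)
  ibaq <- as.matrix(df[, ib_cols, drop = FALSE])
  ibaq[ibaq == 0] <- NA_real_
  rownames(ibaq) <- ids
  colnames(ibaq) <- sub("^iBAQ ", "", ib_cols)
  masses <- stats::setNames(df[["Mol. weight [kDa]"]], ids)
  if (!is.numeric(masses) || any(is.na(masses)) || any(masses <= 0))
    stop("molecular weights must be positive numbers")
  list(ibaq = ibaq, masses = masses, ids = ids)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids. Empty sets and duplicate names are rejected.
#'
#' @param path GMT file path.
#' @return named list of member-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("GMT line(s) with no members in ", path)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicated set name(s) in ", path)
  sets
}

#' Write an expression matrix, sample sheet, or protein table as TSV
#'
#' `write_counts` writes a `gene_id`-keyed matrix; `write_sample_sheet`
#' writes a design; both round-trip losslessly with their readers.
#'
#' @param mat matrix with row names.
#' @param path output TSV path.
#' @export
write_counts <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param design sample design data frame.
#' @export
write_sample_sheet <- function(design, path) {
  df <- data.frame(sample_id = design$sample_id,
                   condition = design$condition,
                   replicate = design$replicate,
                   growth_rate = design$mu, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract the iBAQ matrix and masses from a simulated protein table
#'
#' @param pg a proteinGroups-like data frame
#'   (e.g. [simulate_protein_ibaq()] output).
#' @return as [read_protein_groups()].
#' @export
protein_matrix <- function(pg) {
  ib_cols <- grep("^iBAQ ", names(pg), value = TRUE)
  ibaq <- as.matrix(pg[, ib_cols, drop = FALSE])
  rownames(ibaq) <- pg[["Protein IDs"]]
  colnames(ibaq) <- sub("^iBAQ ", "", ib_cols)
  list(ibaq = ibaq,
       masses = stats::setNames(pg[["Mol. weight [kDa]"]],
                                pg[["Protein IDs"]]),
       ids = pg[["Protein IDs"]])
}
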