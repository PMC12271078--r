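# LD reference panels: reading, dosage correlation, cis windows.

#' Read a genotype-dosage reference panel
#'
#' Accepts either delimited text (individuals in rows, variants in columns,
#' header row of variant ids, dosages in \[0,2\], optional leading sample-id
#' column) or a VCF with GT fields (dosage = ALT-allele count; requires the
#' `vcfR` package). Missing dosages are mean-imputed per variant, the
#' convention for LD panels; a variant with no observed calls is an error.
#'
#' @param path file path (`.vcf` or text detected by content).
#' @return numeric matrix, individuals x variants, column names = variant
#'   ids; attribute `n_imputed` counts imputed cells.
#' @export
read_genotype_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first)) {
    return(read_panel_vcf(path))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  sample_ids <- NULL
  if (ncol(df) > 0 && !is.numeric(df[[1]]) &&
      any(is.na(suppressWarnings(as.numeric(df[[1]]))))) {
    sample_ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  if (!is.null(sample_ids)) rownames(mat) <- sample_ids
  finish_panel(mat)
}

read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF panels requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  # dosage = number of ALT alleles in the GT string; missing -> NA
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  })
  mat <- t(dose)
  colnames(mat) <- ids
  finish_panel(mat)
}

finish_panel <- function(mat) {
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("v%03d", seq_len(ncol(mat)))
  }
  rng <- range(mat, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages outside [0, 2]")
  n_imputed <- 0L
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (all(miss)) stop("all calls missing for variant ", colnames(mat)[j])
    if (any(miss)) {
      mat[miss, j] <- mean(mat[!miss, j])
      n_imputed <- n_imputed + sum(miss)
    }
  }
  attr(mat, "n_imputed") <- n_imputed
  mat
}

#' Pairwise dosage-correlation (LD) matrix
#'
#' Pearson correlation of dosage columns over the requested variants, the
#' quantity clumping and the correlated-instrument estimators condition on.
#'
#' @param panel dosage matrix (individuals x variants, named columns).
#' @param variant_ids ordered variant ids to include (default: all columns).
#' @return an `ld_matrix`: correlation matrix with `dimnames` set, checked
#'   symmetric, unit-diagonal and positive semidefinite to tolerance.
#' @export
compute_ld_matrix <- function(panel, variant_ids = colnames(panel)) {
  if (nrow(panel) < 2) stop("need at least 2 individuals")
  missing_v <- setdiff(variant_ids, colnames(panel))
  if (length(missing_v) > 0) {
    stop("variant(s) absent from panel: ", paste(missing_v, collapse = ", "))
  }
  sub <- panel[, variant_ids, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variant(s): ",
         paste(variant_ids[sds == 0], collapse = ", "))
  }
  ld_matrix(stats::cor(sub))
}

#' Validate and label an LD matrix
#'
#' @param r square correlation matrix with variant ids as dimnames.
#' @return `r` with class `ld_matrix` after checking symmetry (1e-10),
#'   unit diagonal, entries in \[-1,1\] and eigenvalues >= -1e-8.
#' @export
ld_matrix <- function(r) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (max(abs(r - t(r))) > 1e-10) stop("LD matrix not symmetric")
  if (max(abs(diag(r) - 1)) > 1e-10) stop("LD matrix diagonal must be 1")
  if (min(r) < -1 - 1e-10 || max(r) > 1 + 1e-10) {
    stop("LD entries outside [-1, 1]")
  }
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("LD matrix not positive semidefinite")
  }
  structure(r, class = c("ld_matrix", class(matrix())))
}

# Reorder/subset an ld_matrix to the given variant ids.
ld_subset <- function(ld, variant_ids) {
  missing_v <- setdiff(variant_ids, colnames(ld))
  if (length(missing_v) > 0) {
    stop("variant(s) absent from LD matrix: ", paste(missing_v, collapse = ", "))
  }
  out <- ld[variant_ids, variant_ids, drop = FALSE]
  structure(out, class = class(ld))
}

#' Cis window around a gene
#'
#' The interval `[max(1, start - flank_kb * 1000), end + flank_kb * 1000]`
#' on the gene's chromosome, 1-based and inclusive at both ends. The
#' default flank of 500 kb defines the cis-pQTL search and colocalisation
#' window.
#'
#' @param gene one-row data frame or list with `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param flank_kb non-negative flank in kilobases.
#' @return list with `chrom`, `start`, `end` (class `genomic_interval`).
#' @export
cis_window <- function(gene, flank_kb = 500) {
  stopifnot(flank_kb >= 0)
  gene <- as.list(gene)
  structure(list(chrom = as.numeric(gene$chrom),
                 start = max(1, as.numeric(gene$start) - flank_kb * 1000),
                 end = as.numeric(gene$end) + flank_kb * 1000),
            class = "genomic_interval")
}
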