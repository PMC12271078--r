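# GWAS summary-statistic container and delimited-text I/O.

# Canonical column set for one variant-trait association record.
SS_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")

#' Construct a validated GWAS summary-statistics table
#'
#' A `summary_stats` object is a data frame with one row per variant and the
#' fixed columns `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, carrying the trait
#' identity as attributes. `beta` is the per-allele effect in SD units of a
#' quantitative trait, or the log odds ratio for a binary trait.
#'
#' Rows violating hard invariants (non-ACGT or identical alleles, `se <= 0`,
#' `eaf` outside (0,1), chromosome outside 1-22, `pval` outside (0,1],
#' `n < 2`, duplicated variant id) are removed and recorded in the
#' `"rejected"` attribute with a per-row reason. Disagreement between the
#' reported p-value and the two-sided normal approximation from `beta/se`
#' (relative difference of the log10 p beyond 0.15) raises a counted
#' warning only: published GWAS tables round their p-values.
#'
#' @param records data frame holding the columns above.
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param p_consistency_rtol relative tolerance on log10 p for the
#'   beta/se consistency warning.
#' @return A `summary_stats` data frame; attributes `trait_id`,
#'   `trait_type`, `rejected` (data frame of `variant_id`, `reason`).
#' @export
summary_stats <- function(records, trait_id, trait_type = c("quantitative", "binary"),
                          p_consistency_rtol = 0.15) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SS_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[, SS_COLUMNS]
  records$variant_id <- as.character(records$variant_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("chrom", "pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  bases <- c("A", "C", "G", "T")
  flag(!(records$effect_allele %in% bases) | !(records$other_allele %in% bases),
       "non-SNV allele")
  flag(records$effect_allele == records$other_allele, "identical alleles")
  flag(!is.finite(records$se) | records$se <= 0, "nonpositive se")
  flag(!is.finite(records$eaf) | records$eaf <= 0 | records$eaf >= 1,
       "eaf outside (0,1)")
  flag(!is.finite(records$chrom) | records$chrom < 1 | records$chrom > 22 |
         records$chrom != round(records$chrom), "chromosome outside 1-22")
  flag(!is.finite(records$pos) | records$pos < 1, "invalid position")
  flag(!is.finite(records$pval) | records$pval <= 0 | records$pval > 1,
       "p-value outside (0,1]")
  flag(!is.finite(records$n) | records$n < 2, "n below 2")
  flag(!is.finite(records$beta), "non-finite beta")
  flag(duplicated(records$variant_id) & is.na(reason), "duplicate variant id")

  rejected <- data.frame(variant_id = records$variant_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL

  if (nrow(kept) > 0) {
    p_implied <- pmax(z_to_p(kept$beta / kept$se), .Machine$double.xmin)
    l_rep <- log10(kept$pval)
    l_imp <- log10(p_implied)
    denom <- pmax(abs(l_imp), 1)
    n_bad <- sum(abs(l_rep - l_imp) / denom > p_consistency_rtol)
    if (n_bad > 0) {
      warning(sprintf("%d row(s) with p-value inconsistent with beta/se (trait %s)",
                      n_bad, trait_id), call. = FALSE)
    }
  }

  structure(kept,
            trait_id = as.character(trait_id),
            trait_type = trait_type,
            rejected = rejected,
            class = c("summary_stats", "data.frame"))
}

trait_id <- function(ss) attr(ss, "trait_id", exact = TRUE)
trait_type <- function(ss) attr(ss, "trait_type", exact = TRUE) %||% "quantitative"

# Subset a summary_stats object while preserving its attributes.
ss_subset <- function(ss, idx) {
  out <- as.data.frame(ss)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_id = trait_id(ss), trait_type = trait_type(ss),
            rejected = attr(ss, "rejected", exact = TRUE),
            class = c("summary_stats", "data.frame"))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab-separated table (arbitrary source headers supported through
#' `dialect`), maps columns onto the canonical schema and validates rows via
#' [summary_stats()].
#'
#' @param path file path.
#' @param trait_id,trait_type trait identity, as in [summary_stats()].
#' @param dialect optional named character vector mapping canonical column
#'   names (`variant_id`, `chrom`, ...) to the file's header names, e.g.
#'   `c(variant_id = "SNP", pval = "P")`. Unmapped canonical names are
#'   looked up verbatim.
#' @param sep field separator (default tab).
#' @return A validated `summary_stats` object. Errors if a mandatory column
#'   is missing or no row survives validation.
#' @export
read_summary_stats <- function(path, trait_id, trait_type = "quantitative",
                               dialect = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  mapping <- stats::setNames(SS_COLUMNS, SS_COLUMNS)
  if (!is.null(dialect)) mapping[names(dialect)] <- dialect
  missing_cols <- mapping[!(mapping %in% names(raw))]
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- stats::setNames(raw[, unname(mapping), drop = FALSE], names(mapping))
  ss <- summary_stats(df, trait_id = trait_id, trait_type = trait_type)
  if (nrow(ss) == 0) stop("no valid rows in ", path)
  ss
}

#' Write GWAS summary statistics as tab-separated text
#'
#' Inverse of [read_summary_stats()]: fixed canonical header, one row per
#' variant, 17 significant digits so numeric round-trips are exact to well
#' below 1e-12.
#'
#' @param ss a `summary_stats` object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ss, path) {
  stopifnot(inherits(ss, "summary_stats"))
  df <- as.data.frame(ss)
  for (col in c("eaf", "beta", "se", "pval")) {
    df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' BED-like 4-column tab-separated text (`gene_id`, `chrom`, `start`,
#' `end`), 1-based inclusive coordinates in this dialect.
#'
#' @param path file path.
#' @return data frame with those four columns; errors when `start > end`.
#' @export
read_gene_annotation <- function(path) {
  genes <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  needed <- c("gene_id", "chrom", "start", "end")
  if (!all(needed %in% names(genes))) {
    stop("gene annotation needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(genes$start > genes$end)) stop("gene with start > end")
  genes[, needed]
}
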