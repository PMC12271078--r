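# Cross-ancestry and sample-overlap comparison of MR reports.

report_estimates <- function(report) {
  t <- report$table
  t[!is.na(t$estimate),
    c("exposure_id", "outcome_id", "estimate", "se", "p_value",
      "fdr_significant")]
}

#' Compare MR estimates between two ancestries
#'
#' Merges two [run_proteome_wide_mr()] reports on shared exposure-outcome
#' pairs and reports, per pair, both estimates with their standard errors,
#' a concordance flag (same sign and FDR-significant in both) and the
#' heterogeneity test `z = (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)` with
#' its two-sided p. A global Pearson correlation of the estimates is
#' computed over the concordant pairs when at least three are available;
#' otherwise it is omitted with a notice.
#'
#' @param report_a,report_b `pipeline_report` objects.
#' @return list of class `ancestry_comparison` with `table`,
#'   `correlation` (or `NA`), `n_concordant` and `notice`.
#' @export
cross_ancestry_compare <- function(report_a, report_b) {
  a <- report_estimates(report_a)
  b <- report_estimates(report_b)
  m <- merge(a, b, by = c("exposure_id", "outcome_id"),
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("no shared exposure-outcome pairs")
  m$het_z <- (m$estimate_a - m$estimate_b) / sqrt(m$se_a^2 + m$se_b^2)
  m$het_p <- z_to_p(m$het_z)
  m$concordant <- sign(m$estimate_a) == sign(m$estimate_b) &
    m$fdr_significant_a & m$fdr_significant_b

  conc <- m[m$concordant, , drop = FALSE]
  if (nrow(conc) >= 3) {
    correlation <- stats::cor(conc$estimate_a, conc$estimate_b)
    notice <- NULL
  } else {
    correlation <- NA_real_
    notice <- sprintf(
      "correlation omitted: only %d concordant pair(s) (need >= 3)",
      nrow(conc))
  }
  structure(list(table = m, correlation = correlation,
                 n_concordant = nrow(conc), notice = notice),
            class = "ancestry_comparison")
}

#' Sensitivity of MR estimates to outcome-cohort sample overlap
#'
#' Compares a report built on the full outcome GWAS with one built on a
#' non-overlapping (exposure-cohort-excluded) outcome GWAS: Pearson
#' correlation and r-squared of the estimate vectors over shared pairs,
#' plus per-pair deltas.
#'
#' @param report_full,report_nonoverlap `pipeline_report` objects.
#' @return list of class `overlap_sensitivity` with `table` (per-pair
#'   estimates and `delta`), `pearson_r`, `r_squared`, `n_pairs`,
#'   `notice`.
#' @export
sample_overlap_sensitivity <- function(report_full, report_nonoverlap) {
  a <- report_estimates(report_full)
  b <- report_estimates(report_nonoverlap)
  m <- merge(a, b, by = c("exposure_id", "outcome_id"),
             suffixes = c("_full", "_nonoverlap"))
  if (nrow(m) == 0) stop("no shared exposure-outcome pairs")
  m$delta <- m$estimate_full - m$estimate_nonoverlap
  if (nrow(m) >= 3) {
    r <- stats::cor(m$estimate_full, m$estimate_nonoverlap)
    notice <- NULL
  } else {
    r <- NA_real_
    notice <- sprintf("correlation omitted: only %d shared pair(s) (need >= 3)",
                      nrow(m))
  }
  structure(list(table = m, pearson_r = r, r_squared = r^2,
                 n_pairs = nrow(m), notice = notice),
            class = "overlap_sensitivity")
}
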