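# Genetic-instrument selection: significance threshold, greedy LD clumping,
# Steiger directionality, F-statistic and variance explained.

#' Named instrument-selection profiles
#'
#' Three bundled profiles: `strict` (P < 5e-8, clump r2 = 0.001) for the
#' primary proteome-wide MR, `moderate` (P < 5e-6, r2 = 0.1) and `liberal`
#' (P < 1e-4, r2 = 0.4) for the correlated-instrument (GMR) sensitivity
#' analyses.
#'
#' @param name `"strict"`, `"moderate"` or `"liberal"`.
#' @return list with `p_threshold` and `clump_r2`.
#' @export
instrument_profile <- function(name = c("strict", "moderate", "liberal")) {
  name <- match.arg(name)
  switch(name,
         strict = list(p_threshold = 5e-8, clump_r2 = 0.001),
         moderate = list(p_threshold = 5e-6, clump_r2 = 0.1),
         liberal = list(p_threshold = 1e-4, clump_r2 = 0.4))
}

#' Filter variants by association p-value
#'
#' @param ss a [summary_stats()] table (or any data frame with `pval`).
#' @param threshold keep rows with `pval < threshold` (strict), order
#'   preserved.
#' @return the filtered object (possibly empty).
#' @export
select_by_pvalue <- function(ss, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold <= 1)
  idx <- which(ss$pval < threshold)
  if (inherits(ss, "summary_stats")) ss_subset(ss, idx) else ss[idx, , drop = FALSE]
}

# p-value column of either a summary_stats or harmonised_set table.
p_column <- function(x) {
  if ("pval" %in% names(x)) x$pval else if ("p_exp" %in% names(x)) x$p_exp
  else stop("no p-value column found")
}

#' Greedy LD clumping
#'
#' PLINK-style: repeatedly keep the smallest-p remaining candidate and
#' remove every remaining candidate with squared correlation `r^2 >=
#' r2_threshold` against it. Ties on p are broken by ascending
#' (chromosome, position, variant id), making the result invariant to
#' input row order.
#'
#' @param candidates data frame with `variant_id`, a p-value column
#'   (`pval` or `p_exp`) and ideally `chrom`, `pos` for tie-breaking.
#' @param ld an [ld_matrix()] covering every candidate.
#' @param r2_threshold removal threshold on r squared (at 1.0 only exact
#'   duplicates, |r| = 1, are removed).
#' @return the kept rows of `candidates`, attribute `clump_log`: data frame
#'   of (variant_id, action, reason) covering every candidate exactly once.
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.001) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  ids <- candidates$variant_id
  missing_v <- setdiff(ids, colnames(ld))
  if (length(missing_v) > 0) {
    stop("candidate(s) absent from LD matrix: ",
         paste(missing_v, collapse = ", "))
  }
  p <- p_column(candidates)
  chrom <- candidates$chrom %||% rep(0, length(ids))
  pos <- candidates$pos %||% rep(0, length(ids))
  ord <- order(p, chrom, pos, ids)

  r2 <- ld[ids, ids, drop = FALSE]^2
  active <- rep(TRUE, length(ids))
  kept <- character(0)
  log_rows <- list()
  for (i in ord) {
    if (!active[i]) next
    active[i] <- FALSE
    kept <- c(kept, ids[i])
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(variant_id = ids[i], action = "kept",
                 reason = "index variant", stringsAsFactors = FALSE)
    prune <- which(active & r2[i, ] >= r2_threshold - 1e-12)
    for (j in prune) {
      active[j] <- FALSE
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(variant_id = ids[j], action = "removed",
                   reason = paste0("r2 >= ", r2_threshold, " with ", ids[i]),
                   stringsAsFactors = FALSE)
    }
  }
  out <- candidates[match(kept, ids), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clump_log") <- do.call(rbind, log_rows) %||%
    data.frame(variant_id = character(0), action = character(0),
               reason = character(0))
  out
}

#' Variance in a trait explained by one variant, from summary statistics
#'
#' `r^2 = t^2 / (t^2 + n - 2)` with `t = beta / se` — the coefficient of
#' determination of the marginal regression, recovered without needing
#' allele frequency or trait variance. Vectorised.
#'
#' @param beta,se effect and standard error (`se > 0`).
#' @param n sample size (> 2).
#' @return r squared in \[0, 1).
#' @export
variance_explained <- function(beta, se, n) {
  if (any(n <= 2)) stop("n must exceed 2")
  stopifnot(all(se > 0))
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Instrument strength F-statistic
#'
#' `F = (beta/se)^2` for a single variant; the conventional weak-instrument
#' bar is F >= 10.
#'
#' @param beta,se effect and standard error (`se > 0`).
#' @return F value (vectorised).
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Steiger directionality filter
#'
#' Retains a variant iff it explains strictly more variance in the exposure
#' than in the outcome (`r2_exposure > r2_outcome`); exact ties are dropped
#' with reason `"steiger tie"`. The optional `"ztest"` method additionally
#' requires the difference of Fisher-z-transformed correlations to be
#' two-sided significant at `alpha`.
#'
#' @param hs a [harmonise()]d set (needs per-variant n on both sides).
#' @param method `"strict"` (default) or `"ztest"`.
#' @param alpha significance level for the z-test variant.
#' @return the retained subset (a `harmonised_set`), Steiger drops appended
#'   to the `dropped` attribute; columns `r2_exp` and `r2_out` added.
#' @export
steiger_filter <- function(hs, method = c("strict", "ztest"), alpha = 0.05) {
  method <- match.arg(method)
  if (nrow(hs) == 0) return(hs)
  r2_exp <- variance_explained(hs$beta_exp, hs$se_exp, hs$n_exp)
  r2_out <- variance_explained(hs$beta_out, hs$se_out, hs$n_out)
  hs$r2_exp <- r2_exp
  hs$r2_out <- r2_out
  keep <- r2_exp > r2_out
  reason <- ifelse(r2_exp == r2_out, "steiger tie", "steiger direction")
  if (method == "ztest") {
    z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
      sqrt(1 / (hs$n_exp - 3) + 1 / (hs$n_out - 3))
    keep <- keep & z_to_p(z) < alpha
    reason[r2_exp > r2_out & !keep] <- "steiger z-test not significant"
  }
  dropped <- data.frame(variant_id = hs$variant_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  hs_subset(hs, which(keep), extra_dropped = dropped)
}

#' F-statistic filter on a harmonised set
#'
#' Drops instruments with exposure F below `f_min` (default 10).
#'
#' @param hs a [harmonise()]d set.
#' @param f_min minimum F.
#' @return the retained subset with an `f_stat` column; drops appended.
#' @export
f_filter <- function(hs, f_min = 10) {
  if (nrow(hs) == 0) return(hs)
  f <- f_statistic(hs$beta_exp, hs$se_exp)
  hs$f_stat <- f
  keep <- f >= f_min
  dropped <- data.frame(variant_id = hs$variant_id[!keep],
                        reason = sprintf("F < %g", f_min)[rep(1, sum(!keep))],
                        stringsAsFactors = FALSE)
  hs_subset(hs, which(keep), extra_dropped = dropped)
}
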