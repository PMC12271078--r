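# Pairwise Bayesian colocalisation via Wakefield approximate Bayes factors.

#' Wakefield approximate log Bayes factor
#'
#' For a single association with effect `beta`, standard error `se` and a
#' normal effect prior of standard deviation `prior_sd`: with `z =
#' beta/se`, `V = se^2`, `W = prior_sd^2`,
#' `log ABF = 0.5 log(V/(V+W)) + 0.5 z^2 W/(V+W)`.
#'
#' @param beta,se association estimate and standard error (`se > 0`).
#' @param prior_sd effect-scale prior SD (> 0).
#' @return log Bayes factor (vectorised).
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), prior_sd > 0)
  v <- se^2
  w <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * log(v / (v + w)) + 0.5 * z2 * w / (v + w)
}

#' Estimate a quantitative trait's phenotypic SD from summary statistics
#'
#' Regression through the origin of `1/se^2` on `2 eaf (1-eaf) n`; for a
#' standardised trait the slope is `1/sdY^2`.
#'
#' @param se,eaf,n per-variant standard errors, effect-allele frequencies
#'   and sample sizes.
#' @return estimated trait SD.
#' @export
estimate_sdy <- function(se, eaf, n) {
  x <- 2 * eaf * (1 - eaf) * n
  y <- 1 / se^2
  slope <- sum(x * y) / sum(x^2)
  if (!is.finite(slope) || slope <= 0) stop("cannot estimate trait SD")
  sqrt(1 / slope)
}

# Effect-scale prior SD for one trait: 0.15 * sdY for quantitative traits,
# 0.2 on the log-OR scale for binary traits; overridable by the caller.
trait_prior_sd <- function(ss, override = NULL) {
  if (!is.null(override)) return(override)
  if (trait_type(ss) == "binary") return(0.2)
  0.15 * estimate_sdy(ss$se, ss$eaf, ss$n)
}

#' Restrict summary statistics to a genomic interval and common variants
#'
#' Keeps variants inside the (1-based, inclusive) interval whose minor
#' allele frequency is at least `maf_min`; the filter drops `MAF <
#' maf_min` strictly, so a variant at exactly the threshold is retained.
#'
#' @param ss a [summary_stats()] table.
#' @param interval a [cis_window()] result (or list with `chrom`, `start`,
#'   `end`); `NULL` applies only the MAF filter.
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @return the filtered `summary_stats`.
#' @export
regional_slice <- function(ss, interval = NULL, maf_min = 0.05) {
  keep <- rep(TRUE, nrow(ss))
  if (!is.null(interval)) {
    keep <- ss$chrom == interval$chrom &
      ss$pos >= interval$start & ss$pos <= interval$end
  }
  maf <- pmin(ss$eaf, 1 - ss$eaf)
  keep <- keep & !(maf < maf_min)
  ss_subset(ss, which(keep))
}

# Intersect two or three trait slices by variant id and align alleles to
# trait 1's effect allele (ABFs are sign-invariant, but eaf-based filtering
# and reporting use the aligned records). Incompatible alleles are dropped.
align_traits <- function(traits, maf_min = 0) {
  ids <- Reduce(intersect, lapply(traits, function(t) t$variant_id))
  if (length(ids) == 0) stop("no overlapping variants")
  ref <- traits[[1]]
  ref <- ss_subset(ref, match(ids, ref$variant_id))
  out <- list(ref)
  keep <- rep(TRUE, length(ids))
  for (k in seq_along(traits)[-1]) {
    t <- traits[[k]]
    t <- ss_subset(t, match(ids, t$variant_id))
    same <- t$effect_allele == ref$effect_allele &
      t$other_allele == ref$other_allele
    swapped <- t$effect_allele == ref$other_allele &
      t$other_allele == ref$effect_allele
    keep <- keep & (same | swapped)
    t$beta <- ifelse(swapped, -t$beta, t$beta)
    t$eaf <- ifelse(swapped, 1 - t$eaf, t$eaf)
    out[[k]] <- t
  }
  if (maf_min > 0) {
    for (t in out) keep <- keep & !(pmin(t$eaf, 1 - t$eaf) < maf_min)
  }
  if (!any(keep)) stop("no overlapping variants")
  lapply(out, function(t) ss_subset(t, which(keep)))
}

#' Pairwise colocalisation over a region
#'
#' Computes per-variant Wakefield log ABFs for each trait and the
#' posterior over the five hypotheses — H0 no association, H1/H2 one trait
#' only, H3 two distinct causal variants, H4 one shared causal variant —
#' with per-SNP priors `p1`, `p2`, `p12`. All sums run in log space; the
#' H3 sum over ordered distinct pairs uses the product-minus-diagonal
#' identity `S1 S2 - S12`.
#'
#' @param trait1,trait2 regional [summary_stats()] slices.
#' @param priors numeric vector `(p1, p2, p12)`; defaults
#'   `c(1e-4, 1e-4, 1e-5)`.
#' @param maf_min drop variants with MAF below this in either trait.
#' @param prior_sd1,prior_sd2 optional effect-prior SDs (defaults: 0.15 x
#'   estimated trait SD for quantitative traits, 0.2 for binary).
#' @return a `coloc_result`: list with `pph` (named H0..H4 posterior
#'   vector), `n_variants`, `priors`, `per_snp_h4` (per-variant posterior
#'   of being the shared causal variant given H4) and `variant_id`.
#' @export
coloc_abf <- function(trait1, trait2, priors = c(1e-4, 1e-4, 1e-5),
                      maf_min = 0.05, prior_sd1 = NULL, prior_sd2 = NULL) {
  stopifnot(length(priors) == 3, all(priors > 0))
  al <- align_traits(list(trait1, trait2), maf_min = maf_min)
  t1 <- al[[1]]; t2 <- al[[2]]
  labf1 <- wakefield_log_abf(t1$beta, t1$se, trait_prior_sd(trait1, prior_sd1))
  labf2 <- wakefield_log_abf(t2$beta, t2$se, trait_prior_sd(trait2, prior_sd2))
  l1 <- logsumexp(labf1)
  l2 <- logsumexp(labf2)
  l12 <- logsumexp(labf1 + labf2)
  lp <- log(priors)
  logL <- c(H0 = 0,
            H1 = lp[1] + l1,
            H2 = lp[2] + l2,
            H3 = lp[1] + lp[2] + logdiffexp(l1 + l2, l12),
            H4 = lp[3] + l12)
  pph <- exp(logL - logsumexp(logL))
  structure(list(pph = pph / sum(pph),
                 n_variants = nrow(t1),
                 priors = stats::setNames(priors, c("p1", "p2", "p12")),
                 per_snp_h4 = exp(labf1 + labf2 - l12),
                 variant_id = t1$variant_id),
            class = "coloc_result")
}

#' Classify a colocalisation posterior
#'
#' `strong` when PPH4 >= 0.80, `suggestive` when 0.60 <= PPH4 < 0.80,
#' otherwise `none`.
#'
#' @param pph4 posterior probability of a shared causal variant, in
#'   \[0, 1\].
#' @return character scalar (vectorised).
#' @export
classify_coloc <- function(pph4) {
  stopifnot(all(pph4 >= 0 & pph4 <= 1))
  ifelse(pph4 >= 0.80, "strong",
         ifelse(pph4 >= 0.60, "suggestive", "none"))
}
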