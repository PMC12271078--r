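# Three-trait colocalisation over the 15 sharing configurations.

# The 15 configurations of three traits a, b, c: letters grouped together
# share one causal variant; dot-separated groups occupy distinct variants;
# "null" means no trait is associated.
MOLOC_CONFIGS <- c("null", "a", "b", "c", "ab", "ac", "bc", "abc",
                   "a.b", "a.c", "b.c", "ab.c", "ac.b", "bc.a", "a.b.c")

moloc_config_groups <- function(config) {
  if (config == "null") return(list())
  lapply(strsplit(config, ".", fixed = TRUE)[[1]],
         function(g) strsplit(g, "")[[1]])
}

# Per-configuration prior: product over groups of the per-group prior by
# group size (singleton p_one, pair p_two, triple p_three); null has
# prior 1.
moloc_config_log_prior <- function(config, priors) {
  groups <- moloc_config_groups(config)
  if (length(groups) == 0) return(0)
  sum(log(priors[vapply(groups, length, integer(1))]))
}

# Log-likelihood of one configuration given per-trait log-ABF vectors:
# a sum over assignments of causal variants to groups, distinct across
# groups, of the product over groups of the grouped Bayes factors.
# Computed in log space; multi-group sums use inclusion-exclusion over
# the coincidence patterns of the group variants.
moloc_config_loglik <- function(config, labf) {
  groups <- moloc_config_groups(config)
  g <- length(groups)
  if (g == 0) return(0)
  S <- function(traits) logsumexp(Reduce(`+`, labf[traits]))
  if (g == 1) return(S(groups[[1]]))
  if (g == 2) {
    # sum_{v != w} BF_1(v) BF_2(w) = S1 S2 - S12
    logdiffexp(S(groups[[1]]) + S(groups[[2]]),
               S(c(groups[[1]], groups[[2]])))
  } else {
    # three singleton groups: sum over pairwise-distinct triples
    # = Sa Sb Sc - Sab Sc - Sac Sb - Sbc Sa + 2 Sabc
    a <- groups[[1]]; b <- groups[[2]]; c_ <- groups[[3]]
    terms <- c(S(a) + S(b) + S(c_),
               S(c(a, b)) + S(c_),
               S(c(a, c_)) + S(b),
               S(c(b, c_)) + S(a),
               log(2) + S(c(a, b, c_)))
    res <- signed_logsumexp(terms, c(1, -1, -1, -1, 1))
    if (res$sign < 0) -Inf else res$log
  }
}

#' Three-trait Bayesian colocalisation
#'
#' Extends [coloc_abf()] to three regional trait slices, computing the
#' posterior over the 15 sharing configurations (`null`; single-trait
#' `a`, `b`, `c`; shared pairs `ab`, `ac`, `bc`; all shared `abc`;
#' distinct pairs `a.b`, `a.c`, `b.c`; `ab.c`, `ac.b`, `bc.a`; and
#' `a.b.c`). Groups written together share one causal variant; dot
#' separation forces distinct variants. Configuration priors are products
#' of the per-group prior by group size. All assignment sums run in log
#' space with inclusion-exclusion for the distinct-variant constraints.
#'
#' @param trait_a,trait_b,trait_c regional [summary_stats()] slices.
#' @param priors per-SNP priors for a variant associated with exactly
#'   one, two, or all three traits; default `c(1e-4, 1e-6, 1e-7)`.
#' @param maf_min drop variants with MAF below this in any trait.
#' @param prior_sd optional length-3 vector of effect-prior SDs.
#' @return a `moloc_result`: list with `config_posteriors` (named
#'   15-vector summing to 1), `n_variants` and `priors`.
#' @export
moloc <- function(trait_a, trait_b, trait_c, priors = c(1e-4, 1e-6, 1e-7),
                  maf_min = 0.05, prior_sd = NULL) {
  stopifnot(length(priors) == 3, all(priors > 0))
  traits <- list(trait_a, trait_b, trait_c)
  al <- align_traits(traits, maf_min = maf_min)
  labf <- lapply(1:3, function(k) {
    sd_k <- if (!is.null(prior_sd)) prior_sd[k] else NULL
    wakefield_log_abf(al[[k]]$beta, al[[k]]$se,
                      trait_prior_sd(traits[[k]], sd_k))
  })
  names(labf) <- c("a", "b", "c")
  logpost <- vapply(MOLOC_CONFIGS, function(cfg) {
    moloc_config_log_prior(cfg, priors) + moloc_config_loglik(cfg, labf)
  }, numeric(1))
  post <- exp(logpost - logsumexp(logpost))
  structure(list(config_posteriors = post / sum(post),
                 n_variants = nrow(al[[1]]),
                 priors = stats::setNames(priors,
                                          c("p_one", "p_two", "p_three"))),
            class = "moloc_result")
}
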