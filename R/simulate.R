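# Synthetic two-cohort GWAS generator with known ground truth.
#
# Emulates the statistical structure of a cis-pQTL study: an LD-structured
# cis region, a handful of causal variants for a protein exposure measured
# in one cohort, a downstream trait (lipid-like, quantitative or binary)
# measured in a second, disjoint cohort, optional direct variant->outcome
# (pleiotropic) effects and optional reverse causation, plus an independent
# reference panel standing in for an external LD resource.

#' Ground truth for one simulated exposure-outcome system
#'
#' Defaults describe the study conditions the generator emulates: a cis
#' region of 200 variants with AR(1)-decaying LD, 3 true cis-pQTLs, a
#' protein cohort of 10,000 and an outcome cohort of 20,000 individuals,
#' and a causal effect `theta` of the exposure on the outcome (SD per SD,
#' or log-OR per SD for a binary outcome).
#'
#' @param n_variants number of variants in the region.
#' @param maf vector of minor-allele frequencies in (0.01, 0.5); default
#'   uniform draws in (0.05, 0.5) under `seed`.
#' @param ld_rho AR(1) neighbour correlation of the latent genotype process,
#'   in \[0, 1).
#' @param cis_effects per-allele effects of variants on the exposure (SD
#'   units), mostly zero; default places 3 pQTLs of effect 0.35/0.25/0.20 at
#'   evenly spread positions.
#' @param theta causal effect of exposure on outcome.
#' @param pleiotropy vector of direct variant-to-outcome effects.
#' @param reverse_effect outcome-to-exposure effect (reverse causation; the
#'   genetic, noise-free part of the outcome feeds back on the exposure).
#' @param n_exposure,n_outcome disjoint cohort sizes.
#' @param n_ref size of the independent reference panel.
#' @param noise_sd_exposure,noise_sd_outcome residual standard deviations.
#' @param outcome_type `"quantitative"` or `"binary"` (liability threshold).
#' @param prevalence case fraction for a binary outcome.
#' @param chrom,region_start,region_span genomic placement of the region.
#' @param seed integer seed governing every random draw downstream.
#' @return list of class `generative_truth`.
#' @export
generative_truth <- function(n_variants = 200,
                             maf = NULL,
                             ld_rho = 0.8,
                             cis_effects = NULL,
                             theta = 0.3,
                             pleiotropy = 0,
                             reverse_effect = 0,
                             n_exposure = 10000,
                             n_outcome = 20000,
                             n_ref = 1000,
                             noise_sd_exposure = 1,
                             noise_sd_outcome = 1,
                             outcome_type = c("quantitative", "binary"),
                             prevalence = 0.1,
                             chrom = 1, region_start = 1e6, region_span = 1e6,
                             seed = 1) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(n_variants >= 1, ld_rho >= 0, ld_rho < 1,
            n_exposure >= 2, n_outcome >= 2, n_ref >= 2)
  if (is.null(maf)) {
    maf <- local_seed(child_seed(seed, 1),
                      stats::runif(n_variants, 0.05, 0.5))
  }
  stopifnot(length(maf) == n_variants, all(maf > 0.01), all(maf < 0.5 + 1e-12))
  if (is.null(cis_effects)) {
    cis_effects <- numeric(n_variants)
    idx <- unique(pmax(1, round(n_variants * c(0.2, 0.5, 0.8))))
    cis_effects[idx] <- c(0.35, 0.25, 0.20)[seq_along(idx)]
  }
  if (length(pleiotropy) == 1) pleiotropy <- rep(pleiotropy, n_variants)
  if (length(cis_effects) != n_variants || length(pleiotropy) != n_variants) {
    stop("cis_effects and pleiotropy must have length n_variants")
  }
  # crude (LD-ignoring) explained-variance guard for each trait
  vg <- 2 * maf * (1 - maf)
  if (sum(cis_effects^2 * vg) >= 1) stop("cis effects explain variance >= 1")
  if (sum(pleiotropy^2 * vg) + theta^2 >= 1 + noise_sd_outcome^2) {
    stop("outcome explained variance too large")
  }
  pos <- round(seq(region_start, region_start + region_span,
                   length.out = n_variants))
  structure(list(n_variants = n_variants, maf = maf, ld_rho = ld_rho,
                 cis_effects = cis_effects, theta = theta,
                 pleiotropy = pleiotropy, reverse_effect = reverse_effect,
                 n_exposure = n_exposure, n_outcome = n_outcome, n_ref = n_ref,
                 noise_sd_exposure = noise_sd_exposure,
                 noise_sd_outcome = noise_sd_outcome,
                 outcome_type = outcome_type, prevalence = prevalence,
                 chrom = chrom, pos = pos,
                 variant_ids = sprintf("v%04d", seq_len(n_variants)),
                 seed = seed),
            class = "generative_truth")
}

# Non-palindromic allele labels, fixed per variant: effect allele is the
# dosage-counted (ALT-like) allele.
truth_alleles <- function(truth) {
  pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2,
                  byrow = TRUE)
  k <- (seq_len(truth$n_variants) - 1L) %% 4L + 1L
  list(effect = pairs[k, 1], other = pairs[k, 2])
}

#' Simulate an LD-structured dosage panel
#'
#' Each haplotype is an AR(1) latent Gaussian process thresholded at the
#' per-variant MAF quantile; a dosage is the sum of two independent
#' haplotypes, so neighbouring-variant correlation increases with `ld_rho`.
#'
#' @param truth a [generative_truth()].
#' @param n_individuals rows of the returned matrix (>= 2).
#' @param seed integer seed.
#' @return dosage matrix with variant ids as column names.
#' @export
simulate_panel <- function(truth, n_individuals, seed = truth$seed) {
  stopifnot(n_individuals >= 2)
  m <- truth$n_variants
  thr <- stats::qnorm(truth$maf)
  local_seed(seed, {
    dose <- matrix(0, n_individuals, m)
    for (h in 1:2) {
      z <- matrix(stats::rnorm(n_individuals * m), n_individuals, m)
      if (truth$ld_rho > 0 && m > 1) {
        s <- sqrt(1 - truth$ld_rho^2)
        for (j in 2:m) z[, j] <- truth$ld_rho * z[, j - 1] + s * z[, j]
      }
      dose <- dose + (z < rep(thr, each = n_individuals))
    }
    colnames(dose) <- truth$variant_ids
    dose
  })
}

# Vectorised per-variant marginal linear regression: the standard way GWAS
# tables arise. Returns beta/se/p (t-based) and eaf for each column of G.
marginal_gwas_linear <- function(G, y) {
  n <- length(y)
  gm <- colMeans(G)
  sxx <- colSums(G^2) - n * gm^2
  sxy <- as.vector(crossprod(G, y)) - n * gm * mean(y)
  syy <- sum(y^2) - n * mean(y)^2
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- beta / se
  data.frame(beta = beta, se = se,
             pval = pmax(2 * stats::pt(-abs(tval), n - 2), .Machine$double.xmin),
             eaf = gm / 2, n = n)
}

# Per-variant logistic regression for a binary (case/control) trait;
# slower but faithful to the log-OR semantics of disease GWAS.
marginal_gwas_logistic <- function(G, y) {
  n <- length(y)
  out <- t(vapply(seq_len(ncol(G)), function(j) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, G[, j]), y, family = stats::binomial()))
    cf <- fit$coefficients[2]
    # observed-information SE from the weighted cross-product
    X <- cbind(1, G[, j])
    w <- fit$weights
    cov2 <- tryCatch(solve(crossprod(X * sqrt(w)))[2, 2], error = function(e) NA)
    c(cf, sqrt(cov2))
  }, numeric(2)))
  beta <- out[, 1]; se <- out[, 2]
  data.frame(beta = beta, se = se,
             pval = pmax(z_to_p(beta / se), .Machine$double.xmin),
             eaf = colMeans(G) / 2, n = n)
}

gwas_to_ss <- function(stats_df, truth, trait, type) {
  al <- truth_alleles(truth)
  summary_stats(data.frame(
    variant_id = truth$variant_ids, chrom = truth$chrom, pos = truth$pos,
    effect_allele = al$effect, other_allele = al$other,
    eaf = pmin(pmax(stats_df$eaf, 1e-6), 1 - 1e-6),
    beta = stats_df$beta, se = stats_df$se, pval = stats_df$pval,
    n = stats_df$n, stringsAsFactors = FALSE),
    trait_id = trait, trait_type = type)
}

#' Simulate a two-sample GWAS pair with known causal structure
#'
#' Draws three disjoint cohorts (exposure, outcome, reference panel). In
#' every cohort the exposure value is `G %*% cis_effects +
#' reverse_effect * (G %*% pleiotropy) + noise` (the reverse path uses the
#' genetic, noise-free part of the outcome) and the outcome is
#' `theta * exposure + G %*% pleiotropy + noise`; a binary outcome is the
#' liability thresholded at the prevalence quantile with per-variant
#' logistic fits for its summary statistics. Marginal per-variant
#' regressions in each cohort produce the released beta/se/p/eaf/n.
#'
#' @param truth a [generative_truth()].
#' @param seed integer seed (default `truth$seed`).
#' @param exposure_id,outcome_id trait labels on the returned tables.
#' @return list with `exposure` and `outcome` ([summary_stats()]), `panel`
#'   (reference dosage matrix) and `truth`.
#' @export
simulate_two_sample_gwas <- function(truth, seed = truth$seed,
                                     exposure_id = "protein",
                                     outcome_id = "lipid") {
  G_e <- simulate_panel(truth, truth$n_exposure, child_seed(seed, 11))
  G_o <- simulate_panel(truth, truth$n_outcome, child_seed(seed, 12))
  panel <- simulate_panel(truth, truth$n_ref, child_seed(seed, 13))

  draw_exposure <- function(G, eps) {
    as.vector(G %*% truth$cis_effects) +
      truth$reverse_effect * as.vector(G %*% truth$pleiotropy) + eps
  }
  local_seed(child_seed(seed, 14), {
    x_e <- draw_exposure(G_e, stats::rnorm(truth$n_exposure,
                                           sd = truth$noise_sd_exposure))
    x_o <- draw_exposure(G_o, stats::rnorm(truth$n_outcome,
                                           sd = truth$noise_sd_exposure))
    liab <- truth$theta * x_o + as.vector(G_o %*% truth$pleiotropy) +
      stats::rnorm(truth$n_outcome, sd = truth$noise_sd_outcome)
    exp_stats <- marginal_gwas_linear(G_e, x_e)
    if (truth$outcome_type == "binary") {
      y <- as.numeric(liab > stats::quantile(liab, 1 - truth$prevalence))
      out_stats <- marginal_gwas_logistic(G_o, y)
    } else {
      out_stats <- marginal_gwas_linear(G_o, liab)
    }
    list(exposure = gwas_to_ss(exp_stats, truth, exposure_id, "quantitative"),
         outcome = gwas_to_ss(out_stats, truth, outcome_id,
                              truth$outcome_type),
         panel = panel, truth = truth)
  })
}

#' Simulate the same region in two ancestries
#'
#' Shares variant ids across ancestries while allowing different MAF
#' spectra (`shared_maf_shift` is added to ancestry b's MAF, clamped to
#' (0.01, 0.5)), different LD decay, sample sizes and causal effects.
#'
#' @param truth_a,truth_b [generative_truth()] objects with equal
#'   `n_variants`.
#' @param shared_maf_shift additive MAF shift applied to ancestry b.
#' @param seed_a,seed_b per-ancestry seeds.
#' @return list with elements `a` and `b`, each a
#'   [simulate_two_sample_gwas()] result.
#' @export
simulate_two_ancestries <- function(truth_a, truth_b,
                                    shared_maf_shift = 0,
                                    seed_a = truth_a$seed,
                                    seed_b = truth_b$seed) {
  if (truth_a$n_variants != truth_b$n_variants) {
    stop("ancestries must share n_variants")
  }
  truth_b$maf <- pmin(0.499, pmax(0.011, truth_b$maf + shared_maf_shift))
  truth_b$variant_ids <- truth_a$variant_ids
  truth_b$chrom <- truth_a$chrom
  truth_b$pos <- truth_a$pos
  list(a = simulate_two_sample_gwas(truth_a, seed = seed_a),
       b = simulate_two_sample_gwas(truth_b, seed = seed_b))
}

#' Simulate an individual-level phenotype table
#'
#' For the observational stage: protein and lipid levels plus nuisance
#' covariates (age, sex, bmi) and a binary ancestry flag. The generative
#' equation is `lipid = b * protein + interaction_delta * protein *
#' ancestry + ancestry and covariate effects + noise` with `b =
#' truth$theta`, so the main effect and the ancestry interaction are
#' recoverable by the interaction regression. Continuous columns are
#' standardised in expectation (mean 0, SD ~ 1).
#'
#' @param truth a [generative_truth()] (supplies `theta` and the seed).
#' @param interaction_delta ancestry-specific difference in the protein
#'   effect.
#' @param n individuals (>= 50).
#' @param seed integer seed.
#' @return data frame with columns `protein_level`, `lipid_level`,
#'   `ancestry_flag`, `age`, `sex`, `bmi`; class `phenotype_table`.
#' @export
simulate_phenotype_table <- function(truth, interaction_delta = 0, n = 1000,
                                     seed = truth$seed) {
  stopifnot(n >= 50)
  b <- truth$theta
  local_seed(seed, {
    ancestry <- stats::rbinom(n, 1, 0.5)
    age <- stats::rnorm(n)
    sex <- stats::rbinom(n, 1, 0.5)
    bmi <- stats::rnorm(n)
    protein <- stats::rnorm(n)
    cov_part <- 0.10 * age + 0.05 * sex + 0.15 * bmi + 0.05 * ancestry
    expl <- b^2 + interaction_delta^2 / 2 + 0.1^2 + 0.15^2
    noise_sd <- sqrt(max(0.2, 1 - expl))
    lipid <- b * protein + interaction_delta * protein * ancestry +
      cov_part + stats::rnorm(n, sd = noise_sd)
    structure(data.frame(protein_level = protein, lipid_level = lipid,
                         ancestry_flag = ancestry, age = age, sex = sex,
                         bmi = bmi),
              truth_b = b, truth_interaction = interaction_delta,
              class = c("phenotype_table", "data.frame"))
  })
}
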