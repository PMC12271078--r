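# Simulation helpers for the calibration/property tests.

# One forward-simulation replicate: select instruments exactly as the
# primary pipeline does (p < 5e-8, clump r2 = 0.001, harmonise, F >= 10,
# Steiger) and return the primary MR estimate (Wald ratio or IVW).
primary_estimate_once <- function(truth, config = analysis_config()) {
  sim <- simulate_two_sample_gwas(truth)
  sel <- pwmr:::select_pair_instruments(
    sim$exposure, sim$outcome, sim$panel, interval = NULL,
    config$p_primary, config$clump_r2_primary, config$f_min)
  if (sel$status != "ok") return(NULL)
  if (nrow(sel$hs) == 1) mr_wald_ratio(sel$hs) else mr_ivw(sel$hs)
}

# Build a multi-protein study (each protein its own cis region with
# region-specific variant ids) plus a single lipid outcome assembled from
# the per-region outcome scans.
make_protein_study <- function(thetas, seed, n_variants = 30,
                               n_exposure = 4000, n_outcome = 8000,
                               n_ref = 500) {
  exposures <- list(); panels <- list(); gene_rows <- list()
  outcome_parts <- list()
  for (i in seq_along(thetas)) {
    tr <- generative_truth(n_variants = n_variants, theta = thetas[i],
                           n_exposure = n_exposure, n_outcome = n_outcome,
                           n_ref = n_ref, chrom = ((i - 1) %% 22) + 1,
                           region_start = 1e6 + (i - 1) * 5e6,
                           seed = pwmr:::child_seed(seed, i))
    sim <- simulate_two_sample_gwas(tr, exposure_id = paste0("prot", i),
                                    outcome_id = "lipid")
    tag <- function(ss) {
      ss$variant_id <- paste0("g", i, "_", ss$variant_id)
      ss
    }
    exposures[[i]] <- summary_stats(tag(as.data.frame(sim$exposure)),
                                    paste0("prot", i))
    outcome_parts[[i]] <- tag(as.data.frame(sim$outcome))
    pan <- sim$panel
    colnames(pan) <- paste0("g", i, "_", colnames(pan))
    panels[[paste0("prot", i)]] <- pan
    gene_rows[[i]] <- data.frame(gene_id = paste0("prot", i),
                                 chrom = tr$chrom,
                                 start = tr$pos[round(n_variants * 0.4)],
                                 end = tr$pos[round(n_variants * 0.6)])
  }
  list(exposures = exposures,
       outcome = summary_stats(do.call(rbind, outcome_parts), "lipid"),
       panels = panels, genes = do.call(rbind, gene_rows))
}

# Region truth with a single causal variant for the exposure and a direct
# (pleiotropic) outcome effect at `outcome_idx` (same index -> shared
# causal variant; distant index -> distinct causal variants).
coloc_region_truth <- function(seed, shared, n_variants = 50,
                               exposure_idx = 18, outcome_idx = 42,
                               n_exposure = 10000, n_outcome = 20000) {
  cis <- numeric(n_variants); cis[exposure_idx] <- 0.3
  ple <- numeric(n_variants)
  ple[if (shared) exposure_idx else outcome_idx] <- 0.15
  maf <- pwmr:::local_seed(pwmr:::child_seed(seed, 3),
                           stats::runif(n_variants, 0.1, 0.5))
  generative_truth(n_variants = n_variants, maf = maf, ld_rho = 0.8,
                   cis_effects = cis, theta = 0, pleiotropy = ple,
                   n_exposure = n_exposure, n_outcome = n_outcome,
                   n_ref = 400, seed = seed)
}
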