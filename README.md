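# pwmr — proteome-wide Mendelian randomisation with colocalisation

`pwmr` is an R package for summary-statistic causal inference linking
circulating plasma proteins to lipid fractions (HDL-C, LDL-C, non-HDL-C,
total cholesterol, triglycerides) and cardiovascular outcomes. It is
aimed at analysts running ancestry-aware protein screens from published
GWAS summary statistics: a protein GWAS in one cohort, outcome GWAS in
another, an LD reference panel, and nothing individual-level.

## What it computes

For an exposure with per-variant effects β̂_X (SE σ_X) and an outcome
with β̂_Y (SE σ_Y), the package estimates the causal effect θ of the
exposure on the outcome from cis-pQTL instruments:

- **Wald ratio** (1 instrument): θ̂ = β̂_Y/β̂_X, SE |σ_Y/β̂_X|;
- **IVW** (k ≥ 2): weighted regression of β̂_Y on β̂_X through the
  origin, weights 1/σ_Y²; Cochran's Q and multiplicative random-effects
  SE inflation √max(1, Q/(k−1));
- **MR-Egger** and **weighted median** (k ≥ 3) as pleiotropy-robust
  sensitivity estimators;
- **gIVW / gEgger**: generalised least squares under the LD-induced
  outcome covariance Σᵢⱼ = σ_Yi σ_Yj rᵢⱼ, for correlated instruments
  selected under liberal thresholds;
- **Pairwise colocalisation** from Wakefield approximate Bayes factors,
  log ABF = ½ log(V/(V+W)) + ½ z² W/(V+W), with posteriors PPH0–PPH4
  (PPH4 ≥ 0.80 strong, 0.60–0.80 suggestive);
- **Three-trait colocalisation** over all 15 sharing configurations with
  per-SNP priors 1e-4 / 1e-6 / 1e-7;
- Instrument selection: P < 5e-8 with greedy LD clumping at r² = 0.001
  (plus moderate 5e-6/0.1 and liberal 1e-4/0.4 profiles), Steiger
  directionality filtering via r² = t²/(t²+n−2), and an F ≥ 10
  weak-instrument bar;
- Per-outcome Benjamini–Hochberg FDR and Bonferroni control, reverse MR,
  cross-ancestry comparison with per-pair heterogeneity z-tests, and an
  observational protein×ancestry interaction regression.

A ground-truth synthetic GWAS generator (AR(1)-latent LD panels, disjoint
cohorts, configurable causal effects, pleiotropy and reverse causation)
makes the whole chain testable end to end without any data downloads.

## Worked example

Simulate one protein region with a true causal effect θ = 0.3 on a lipid
outcome, then run the full pipeline:

```r
library(pwmr)
tr <- generative_truth(n_variants = 60, theta = 0.3, seed = 42)
sim <- simulate_two_sample_gwas(tr)
genes <- data.frame(gene_id = "protein", chrom = 1,
                    start = 1.4e6, end = 1.6e6)
report <- run_proteome_wide_mr(list(sim$exposure), list(sim$outcome),
                               sim$panel, genes, analysis_config(seed = 7))
report
#> MR pipeline report: 1 pair(s), 1 FDR-significant, 1 validated
report$table[, c("method", "n_instruments", "estimate", "se", "p_value",
                 "q_fdr", "pph4", "coloc_class", "gmr_estimate", "validated")]
#>   method n_instruments estimate   se  p_value    q_fdr pph4 coloc_class
#> 1    ivw             2    0.333 0.06 2.98e-08 2.98e-08    1      strong
#>   gmr_estimate validated
#> 1        0.338      TRUE
```

Two clumped cis-pQTLs survive selection; the IVW estimate 0.333 (SE
0.060) recovers the generating effect 0.3 within sampling error; the
region colocalises strongly (PPH4 = 1.0) because the exposure's causal
variants drive the outcome through the simulated causal path; the
liberal-profile gIVW agrees (0.338), so the pair carries the full
evidence triangle (`validated = TRUE`).

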