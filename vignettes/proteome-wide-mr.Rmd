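---
title: "Proteome-wide Mendelian randomisation with colocalisation: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-wide Mendelian randomisation with colocalisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmr)
```

# The scientific problem

Circulating plasma proteins are prime candidates both as biomarkers and as
drug targets for dyslipidaemia and downstream cardiovascular disease.
`pwmr` implements a summary-statistic causal-inference chain for asking, at
proteome scale, whether genetically predicted protein levels causally
affect lipid fractions (HDL-C, LDL-C, non-HDL-C, total cholesterol,
triglycerides) or cardiovascular outcomes, using only published GWAS
summary statistics and an LD reference panel — no individual-level data.
The design questions it targets are those of an ancestry-aware protein
screen: a modest protein GWAS in the population of interest, much larger
outcome GWAS, cis-pQTL instruments, and a need to triangulate every
association across independent lines of evidence before believing it.

# The causal model and its assumptions

Two-sample Mendelian randomisation treats genetic variants as instruments
for an exposure $X$ (a protein level, in SD units) measured in one cohort,
with the outcome $Y$ measured in a second, non-overlapping cohort. For
variant $i$ with exposure association $\hat\beta_{Xi}$ (SE $\sigma_{Xi}$)
and outcome association $\hat\beta_{Yi}$ (SE $\sigma_{Yi}$), the
instrumental estimate of the causal effect $\theta$ is built from the Wald
ratios $\hat\beta_{Yi}/\hat\beta_{Xi}$. Validity rests on the three
instrumental-variable assumptions: relevance (the variant predicts the
protein — enforced here by the $P$-threshold and the $F \ge 10$ bar),
independence from confounders (plausible for germline variants), and
exclusion restriction (no pathway to the outcome other than through the
protein — addressed by restricting to cis variants, by the Egger intercept
test, and by colocalisation).

Using cis variants only — within ±500 kb of the protein's cognate gene —
is the key structural choice: cis-pQTLs are strong, biologically
proximate, and far less likely to act through other gene products than
trans associations.

# Estimators

* **Wald ratio** (one instrument): $\hat\theta = \hat\beta_Y/\hat\beta_X$,
  first-order SE $|\sigma_Y/\hat\beta_X|$ (second-order form available).
* **IVW** ($k \ge 2$): weighted regression of $\hat\beta_Y$ on
  $\hat\beta_X$ through the origin with weights $1/\sigma_{Yi}^2$;
  identical to the inverse-variance meta-analysis of Wald ratios.
* **MR-Egger** ($k \ge 3$): the same regression with a free intercept;
  a non-zero intercept estimates directional pleiotropy. Instruments are
  flipped to positive exposure effect first (required for identifiability
  of the intercept).
* **Weighted median** ($k \ge 3$): weighted median of Wald ratios,
  consistent while at least half the weight is valid; SE from a seeded
  parametric bootstrap.
* **gIVW / gEgger**: the generalised-least-squares forms for *correlated*
  instruments, with outcome covariance
  $\Sigma_{ij} = \sigma_{Yi}\sigma_{Yj} r_{ij}$ taken from the LD matrix
  $r$ of a reference panel. Under identity LD they reduce exactly to
  IVW/MR-Egger; this reduction is asserted in the test suite at 1e-10.

Heterogeneity is summarised by Cochran's $Q$, and all multi-instrument
standard errors carry a multiplicative random-effects inflation
$\sqrt{\max(1, Q/\mathrm{df})}$ — multiplicative rather than additive
because that is the mainstream two-sample MR convention, with a floor at 1
so the model never claims more precision than the fixed-effect fit. The
first-order ratio weights are the default; second-order weights are a
configuration switch. Binary outcomes are carried as log odds ratios
internally and only exponentiated for reporting.

# Instrument selection

Selection follows the standard cis-pQTL recipe, bundled as three named
profiles:

| profile | $P$ threshold | clump $r^2$ | use |
|---|---|---|---|
| strict | $5\times10^{-8}$ | 0.001 | primary screen |
| moderate | $5\times10^{-6}$ | 0.1 | GMR sensitivity |
| liberal | $1\times10^{-4}$ | 0.4 | GMR sensitivity |

Clumping is the greedy PLINK-style algorithm: keep the smallest-$p$
candidate, drop everything with $r^2$ at or above the threshold against
it, repeat. Ties on $p$ break by (chromosome, position, variant id) so the
result does not depend on input row order. Steiger filtering retains a
variant only when it explains strictly more variance in the exposure than
in the outcome, with $r^2 = t^2/(t^2+n-2)$ recovered from summary
statistics alone — this formula needs neither allele frequency nor trait
variance, which is why it is used here. An exact tie is dropped. A
Fisher-z significance variant of the Steiger rule exists behind
`method = "ztest"` but is off by default, because the strict inequality is
the common published form and the z-test's extra conservativeness is not
obviously wanted at cis loci.

# Harmonisation choices

Exposure and outcome tables are joined by variant id; swapped allele
reports negate the outcome beta and reflect its allele frequency;
strand-complement reports are resolved through base complementing.
Palindromic variants (A/T, C/G) cannot be strand-resolved from alleles, so
they are oriented by allele-frequency agreement and dropped as
"ambiguous palindrome" when either trait's EAF lies within 0.08 of 0.5
(i.e. in [0.42, 0.58]) — the conventional band; the source analyses do not
state their rule, so this default is a package choice, not a citation.
Indels are rejected at read time: the instruments of interest are SNVs and
excluding indels removes a family of harmonisation ambiguities. All drops
are recorded with reasons rather than raised.

# Colocalisation

An MR hit can be driven by two distinct causal variants in LD. Pairwise
Bayesian colocalisation computes, for every variant, the Wakefield
approximate Bayes factor

$$\log \mathrm{ABF} = \tfrac12\log\frac{V}{V+W} + \tfrac12 z^2\frac{W}{V+W},$$

with $V$ the squared SE, $W$ the squared prior effect SD, and sums these
over the five hypotheses H0–H4 with per-SNP priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$. PPH4 ≥ 0.80 is reported as
strong colocalisation and [0.60, 0.80) as suggestive. The prior effect SD
defaults to $0.15\,\mathrm{sd}_Y$ for quantitative traits (with
$\mathrm{sd}_Y$ estimated from the regression of $1/\mathrm{se}^2$ on
$2\,\mathrm{eaf}(1-\mathrm{eaf})n$) and 0.2 on the log-OR scale for binary
traits; both are overridable, and since the source analyses do not print
their priors these defaults are flagged as assumptions. Rare variants
(MAF < 0.05) are dropped from every colocalisation window; the filter is
strict, so MAF exactly 0.05 stays.

The three-trait extension evaluates all 15 sharing configurations of
traits a, b, c (e.g. `abc` = one variant shared by all three; `ab.c` =
a and b share one variant, c has a distinct one) with per-SNP priors
$10^{-4}/10^{-6}/10^{-7}$ for a variant associated with one/two/three
traits. Every hypothesis sum runs in log space: H3-type "distinct
variant" sums use the product-minus-diagonal identity
$S_1S_2 - S_{12}$, and the fully distinct three-variant sum uses
inclusion–exclusion
$S_aS_bS_c - S_{ab}S_c - S_{ac}S_b - S_{bc}S_a + 2S_{abc}$, implemented
with a signed log-sum-exp. Both are verified against explicit assignment
enumeration on small regions (≤ 12 variants pairwise at 1e-10 log
posterior, ≤ 8 variants three-trait at 1e-8).

# The pipeline and evidence tiering

`run_proteome_wide_mr()` chains the stages per exposure–outcome pair and
applies Benjamini–Hochberg FDR *separately within each outcome* across
exposures (each lipid fraction or disease outcome is its own testing
family; Bonferroni values are reported alongside). FDR-significant pairs
then receive the sensitivity estimators, colocalisation, and GMR at the
liberal and moderate profiles. A pair is flagged `validated` only when it
is FDR-significant *and* colocalises (strong or suggestive) *and* the
liberal-profile gIVW is same-signed and significant at 0.05 — the
triangulation rule; "GMR consistent" is defined as sign plus significance
because a sign-only rule proved too weak to mean anything under the null.
`run_reverse_mr()` applies the identical machinery with genome-wide
instead of cis instrument selection, for the lipid-to-protein direction.
Cross-ancestry comparison reports per-pair heterogeneity
$z = (\beta_a-\beta_b)/\sqrt{se_a^2+se_b^2}$ and a global Pearson
correlation over concordant (same-sign, both-significant) pairs, matching
how replication across ancestries is usually summarised.

# What the synthetic-data generator emulates

`generative_truth()` + `simulate_two_sample_gwas()` generate the study
structure end-to-end: three disjoint cohorts (exposure, outcome,
reference panel); an LD-structured cis region built by thresholding an
AR(1) latent Gaussian per haplotype at the MAF quantile, so one parameter
(`ld_rho`) tunes LD decay; a handful of true cis-pQTLs; a causal effect
`theta`; optional direct variant-outcome (pleiotropic) effects; optional
reverse causation, where the genetic part of the outcome feeds back on
the exposure; and per-variant marginal regressions producing the released
beta/SE/p/EAF/N, because that is how real GWAS tables arise. Binary
outcomes are thresholded liabilities with per-variant logistic fits, so
their betas are genuine log odds ratios.

Default conditions: 200 variants per region, 3 cis-pQTLs with per-allele
effects 0.35/0.25/0.20 SD, MAF uniform on (0.05, 0.5), `ld_rho` 0.8,
cohort sizes 10,000 (exposure) / 20,000 (outcome) / 1,000 (panel). These
sizes give the true pQTLs $z$ scores around 15–20, comfortably past the
genome-wide threshold, while the exposure cohort remains modest — the
regime of a well-powered but not enormous proteomics GWAS. What the
generator does **not** emulate: empirical (non-stationary) LD, allele
frequency spectra of real populations, genome-wide polygenicity,
imputation error, or sample overlap beyond a disjoint/shared toggle. A
passing simulation suite therefore demonstrates the statistical machinery
is correct and calibrated under the stated generative model, not that any
particular real-data finding is reproduced.

# Numerical choices

* All colocalisation sums in log space; signed log-sum-exp for
  inclusion–exclusion; ties in `logdiffexp` collapse to $-\infty$ rather
  than NaN.
* The GLS covariance $\Sigma$ is ridge-regularised when near-singular:
  $\lambda\,\mathrm{diag}(\Sigma)$ with $\lambda$ from $10^{-6}$
  escalating tenfold to $10^{-2}$, each escalation emitting a warning —
  never silent, and failure past $10^{-2}$ is an error.
* Clump removal compares $r^2 \ge$ threshold with a $10^{-12}$ slack so
  exact duplicates ($r^2$ = 1 up to floating point) are removed at
  threshold 1.0.
* Missing dosages are mean-imputed per variant before correlation, the
  usual LD-panel handling; an all-missing variant is an error.
* The reported p/beta/se consistency check is a warning, not an error,
  because published tables round p-values.
* Every stochastic routine (bootstrap, generators) takes a seed and
  restores the caller's RNG state; pipeline sub-seeds derive from the
  config seed and the pair's *identity*, so permuting input lists cannot
  change any result.

# Problem sizes used in the validation suite

The test suite runs: estimator-vs-oracle checks on 50 random instances
per estimator; causal-effect recovery at $\theta = 0.3$ over 200
replicates (60-variant regions, 10,000/20,000 cohorts) requiring mean
bias ≤ 0.03 and 90–98% CI coverage; type-I error over 1,000 null
replicates (30-variant regions) requiring a 3.5–6.5% rejection rate at
$\alpha = 0.05$; Egger-intercept recovery and weighted-median robustness
over 200 summary-level replicates; colocalisation calibration over 50
shared and 50 distinct-variant regions (50 variants, causal variants 24
positions apart so their $r^2 < 0.01$); Steiger retention/removal over
100 replicates each; 1,000 random multiple-testing vectors; end-to-end
recovery on 25 replicates of a 20-protein panel (3 causal at
$\theta = 0.4$, cohorts 4,000/8,000); and the ancestry contrast
$\theta = 0.16$ vs $0.37$ over 100 replicates with outcome cohorts of
40,000/60,000 plus 100 interaction-regression replicates at n = 50,000.
Region sizes and replicate counts per block were chosen once to keep each
quantity's Monte-Carlo error well inside its acceptance band at
desk-scale runtimes. `scripts/acceptance.R` recomputes the same
quantities at reduced replicate counts and writes them as JSON.

# Known limitations

* Single-causal-variant assumption in colocalisation (no SuSiE-style
  multi-signal decomposition); a region with two shared signals is
  summarised, not decomposed.
* No HEIDI-style outlier removal, MR-PRESSO, or multivariable MR.
* No liftover, multi-allelic decomposition, X-chromosome or MHC handling.
* The weighted median's bootstrap SE ignores LD between instruments, so
  at the liberal clumping profile it is approximate; gIVW/gEgger are the
  correlated-instrument workhorses.
* Cohort overlap between exposure and outcome GWAS biases two-sample MR;
  the package quantifies sensitivity via `sample_overlap_sensitivity()`
  but cannot correct for it.

# A worked example

```{r example}
tr <- generative_truth(n_variants = 60, theta = 0.3, seed = 42)
sim <- simulate_two_sample_gwas(tr)
genes <- data.frame(gene_id = "protein", chrom = 1,
                    start = 1.4e6, end = 1.6e6)
report <- run_proteome_wide_mr(list(sim$exposure), list(sim$outcome),
                               sim$panel, genes,
                               analysis_config(seed = 7))
report$table[, c("method", "n_instruments", "estimate", "se", "p_value",
                 "q_fdr", "pph4", "coloc_class", "validated")]
```

The IVW estimate recovers the generating effect of 0.3 within sampling
error, the region colocalises strongly (the exposure's causal variants
drive the outcome through the simulated causal path), and the pair passes
the full evidence triangle.
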