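Package: pwmr
Title: Proteome-Wide Two-Sample Mendelian Randomisation with Colocalisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Summary-statistic causal inference linking circulating plasma
    proteins to lipid fractions and cardiovascular outcomes: cis-pQTL
    instrument selection with greedy LD clumping, Steiger directionality and
    F-statistic filtering; two-sample Mendelian randomisation estimators
    (Wald ratio, inverse-variance weighted, MR-Egger, weighted median) and
    their correlated-instrument generalisations (gIVW, gEgger); pairwise and
    three-trait Bayesian colocalisation via Wakefield approximate Bayes
    factors; Benjamini-Hochberg and Bonferroni multiple-testing control;
    reverse MR, cross-ancestry comparison and an observational interaction
    regression; plus a synthetic GWAS summary-statistic generator with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
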