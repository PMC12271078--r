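# Shared fixtures and independent brute-force oracles.

# --- fixtures -------------------------------------------------------------

make_ss_df <- function(n, seed = 1, chrom = 1, pos_start = 1e6,
                       alleles = c("A", "G")) {
  set.seed(seed)
  beta <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.01, 0.05)
  data.frame(
    variant_id = sprintf("rs%04d", seq_len(n)),
    chrom = chrom, pos = pos_start + seq_len(n) * 1000,
    effect_allele = alleles[1], other_allele = alleles[2],
    eaf = runif(n, 0.1, 0.9), beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), n = 10000,
    stringsAsFactors = FALSE)
}

make_ss <- function(n, seed = 1, trait = "trait", type = "quantitative", ...) {
  summary_stats(make_ss_df(n, seed, ...), trait_id = trait, trait_type = type)
}

# harmonised set straight from instrument-level numbers
make_hs <- function(beta_exp, beta_out, se_exp, se_out,
                    n_exp = 10000, n_out = 20000,
                    ids = sprintf("rs%04d", seq_along(beta_exp))) {
  k <- length(beta_exp)
  structure(data.frame(
    variant_id = ids, chrom = 1, pos = seq_len(k) * 1000,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp, p_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
    n_exp = n_exp, eaf_exp = 0.3,
    beta_out = beta_out, se_out = se_out,
    p_out = 2 * pnorm(-abs(beta_out / se_out)), n_out = n_out, eaf_out = 0.3,
    flipped = FALSE, stringsAsFactors = FALSE),
    exposure_id = "exp", outcome_id = "out", outcome_type = "quantitative",
    dropped = data.frame(variant_id = character(0), reason = character(0)),
    class = c("harmonised_set", "data.frame"))
}

# random positive-semidefinite correlation matrix with unit diagonal
random_corr <- function(k, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(k * (k + 2)), k + 2, k)
  S <- crossprod(A)
  d <- sqrt(diag(S))
  r <- S / outer(d, d)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  dimnames(r) <- list(sprintf("rs%04d", seq_len(k)), sprintf("rs%04d", seq_len(k)))
  r
}

# summary_stats slice for coloc tests, built from z-scores
ss_from_z <- function(z, se = 0.02, trait = "t", n = 10000, eaf = NULL,
                      type = "quantitative") {
  m <- length(z)
  if (is.null(eaf)) eaf <- rep(0.3, m)
  summary_stats(data.frame(
    variant_id = sprintf("rs%04d", seq_len(m)), chrom = 1,
    pos = 1e6 + seq_len(m) * 1000,
    effect_allele = "A", other_allele = "G", eaf = eaf,
    beta = z * se, se = se, pval = pmax(2 * pnorm(-abs(z)), 1e-300), n = n,
    stringsAsFactors = FALSE), trait_id = trait, trait_type = type)
}

# --- oracles --------------------------------------------------------------

# weighted least squares through the origin (IVW oracle)
oracle_wls_origin <- function(x, y, w) {
  est <- sum(w * x * y) / sum(w * x^2)
  list(estimate = est, se = sqrt(1 / sum(w * x^2)))
}

# weighted least squares with intercept (Egger oracle), fixed-effect SEs
oracle_wls_intercept <- function(x, y, w) {
  X <- cbind(1, x)
  cv <- solve(t(X) %*% (w * X))
  cf <- cv %*% t(X) %*% (w * y)
  list(intercept = cf[1], slope = cf[2], cov = cv)
}

# GLS oracles under covariance sigma
oracle_gls_origin <- function(x, y, sigma) {
  si <- solve(sigma)
  xsx <- as.numeric(t(x) %*% si %*% x)
  list(estimate = as.numeric(t(x) %*% si %*% y) / xsx, se = sqrt(1 / xsx))
}

oracle_gls_intercept <- function(x, y, sigma) {
  si <- solve(sigma)
  X <- cbind(1, x)
  cv <- solve(t(X) %*% si %*% X)
  cf <- cv %*% t(X) %*% si %*% y
  list(intercept = cf[1], slope = cf[2], cov = cv)
}

# brute-force pairwise Pearson correlation (LD oracle)
oracle_cor_matrix <- function(panel) {
  m <- ncol(panel)
  r <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) {
    r[i, j] <- cor(panel[, i], panel[, j])
  }
  r
}

# brute-force BH step-up q-values
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)  # rank of p[i]
    cand <- sapply(rank_i:m, function(j) p[ord[j]] * m / j)
    q[i] <- min(1, min(cand))
  }
  q
}

# brute-force pairwise coloc by enumerating single- and pair-variant
# causal assignments in linear space (small regions only)
oracle_coloc <- function(labf1, labf2, priors) {
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  Q <- length(bf1)
  L0 <- 1
  L1 <- priors[1] * sum(bf1)
  L2 <- priors[2] * sum(bf2)
  L3 <- 0
  for (i in 1:Q) for (j in 1:Q) if (i != j) L3 <- L3 + bf1[i] * bf2[j]
  L3 <- priors[1] * priors[2] * L3
  L4 <- priors[3] * sum(bf1 * bf2)
  L <- c(L0, L1, L2, L3, L4)
  L / sum(L)
}

# brute-force three-trait coloc: enumerate every assignment of each
# configuration's groups to variants (distinct across groups)
oracle_moloc <- function(labf, priors) {
  bf <- lapply(labf, exp)
  Q <- length(bf[[1]])
  configs <- c("null", "a", "b", "c", "ab", "ac", "bc", "abc",
               "a.b", "a.c", "b.c", "ab.c", "ac.b", "bc.a", "a.b.c")
  gbf <- function(traits, v) {
    prod(sapply(traits, function(t) bf[[t]][v]))
  }
  lik <- sapply(configs, function(cfg) {
    if (cfg == "null") return(1)
    groups <- lapply(strsplit(cfg, ".", fixed = TRUE)[[1]],
                     function(g) strsplit(g, "")[[1]])
    g <- length(groups)
    prior <- prod(priors[sapply(groups, length)])
    total <- 0
    if (g == 1) {
      for (v in 1:Q) total <- total + gbf(groups[[1]], v)
    } else if (g == 2) {
      for (v in 1:Q) for (w in 1:Q) if (v != w) {
        total <- total + gbf(groups[[1]], v) * gbf(groups[[2]], w)
      }
    } else {
      for (v in 1:Q) for (w in 1:Q) for (u in 1:Q) {
        if (v != w && v != u && w != u) {
          total <- total + gbf(groups[[1]], v) * gbf(groups[[2]], w) *
            gbf(groups[[3]], u)
        }
      }
    }
    prior * total
  })
  lik / sum(lik)
}

# OLS via normal equations (observational-regression oracle)
oracle_ols <- function(X, y) {
  cf <- solve(t(X) %*% X) %*% t(X) %*% y
  resid <- y - X %*% cf
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  list(coef = as.vector(cf), se = sqrt(diag(s2 * solve(t(X) %*% X))))
}
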