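# MR estimators against arithmetic cases and brute-force (G)LS oracles.

test_that("Wald ratio and its delta-method standard errors", {
  hs <- make_hs(0.5, 0.25, 0.1, 0.05)
  r <- mr_wald_ratio(hs)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.1)
  expect_equal(r$ci_low, 0.5 - 1.959964 * 0.1, tolerance = 1e-6)
  expect_equal(r$p_value, 2 * pnorm(-5), tolerance = 1e-9)
  r2 <- mr_wald_ratio(hs, second_order = TRUE)
  expect_equal(r2$se, sqrt(0.05^2 / 0.5^2 + 0.25^2 * 0.1^2 / 0.5^4),
               tolerance = 1e-9)
  # with equal exposure/outcome SEs of 0.05 the closed form gives 0.1118
  r3 <- mr_wald_ratio(make_hs(0.5, 0.25, 0.05, 0.05), second_order = TRUE)
  expect_equal(r3$se, sqrt(0.0125), tolerance = 1e-9)
  expect_equal(r3$se, 0.1118, tolerance = 1e-3)
  expect_equal(mr_wald_ratio(make_hs(0.5, 0, 0.1, 0.05))$estimate, 0)
  expect_error(mr_wald_ratio(make_hs(0, 0.1, 0.1, 0.05)), "undefined")
})

test_that("IVW equals the inverse-variance mean and the WLS oracle", {
  # two ratios 0.4, 0.6 with first-order se 0.1 each
  hs <- make_hs(c(1, 1), c(0.4, 0.6), c(0.05, 0.05), c(0.1, 0.1))
  r <- mr_ivw(hs)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se / r$re_scaling, sqrt(1 / 200), tolerance = 1e-9)
  # identical ratios: Q = 0, no random-effects inflation
  hs0 <- make_hs(c(1, 2, 4), c(0.3, 0.6, 1.2), rep(0.05, 3), rep(0.1, 3))
  r0 <- mr_ivw(hs0)
  expect_equal(r0$estimate, 0.3)
  expect_equal(r0$q_statistic, 0, tolerance = 1e-20)
  expect_equal(r0$re_scaling, 1)
  expect_error(mr_ivw(make_hs(1, 1, 0.1, 0.1)), "wald_ratio")
  # random instances vs brute-force weighted regression through the origin
  for (s in 1:5) {
    set.seed(s)
    k <- 10
    hs <- make_hs(rnorm(k, 0.3, 0.1), rnorm(k, 0.1, 0.05),
                  runif(k, 0.01, 0.05), runif(k, 0.01, 0.05))
    got <- mr_ivw(hs)
    want <- oracle_wls_origin(hs$beta_exp, hs$beta_out, 1 / hs$se_out^2)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-10)
    expect_equal(got$se / got$re_scaling, want$se, tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers slope and pleiotropy intercept", {
  bx <- c(0.2, 0.4, 0.6)
  hs <- make_hs(bx, 0.3 * bx, rep(0.02, 3), rep(0.05, 3))
  r <- mr_egger(hs)
  expect_equal(r$estimate, 0.3, tolerance = 1e-10)
  expect_equal(r$intercept, 0, tolerance = 1e-10)
  # constant pleiotropy shifts the intercept only
  hs2 <- make_hs(bx, 0.3 * bx + 0.05, rep(0.02, 3), rep(0.05, 3))
  r2 <- mr_egger(hs2)
  expect_equal(r2$estimate, 0.3, tolerance = 1e-10)
  expect_equal(r2$intercept, 0.05, tolerance = 1e-10)
  expect_error(mr_egger(make_hs(c(1, 2), c(1, 2), c(0.1, 0.1), c(0.1, 0.1))),
               ">= 3")
  # random instances vs brute-force weighted least squares
  for (s in 1:5) {
    set.seed(100 + s)
    k <- 10
    hs <- make_hs(abs(rnorm(k, 0.3, 0.1)) + 0.05, rnorm(k, 0.1, 0.05),
                  runif(k, 0.01, 0.05), runif(k, 0.01, 0.05))
    got <- mr_egger(hs)
    want <- oracle_wls_intercept(hs$beta_exp, hs$beta_out, 1 / hs$se_out^2)
    expect_equal(got$estimate, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  }
})

test_that("weighted median interpolates ratios and is bootstrap-deterministic", {
  hs0 <- make_hs(c(1, 1, 1), c(0.3, 0.3, 0.3), rep(0.05, 3), rep(0.1, 3))
  expect_equal(mr_weighted_median(hs0, n_boot = 50)$estimate, 0.3)
  hs1 <- make_hs(c(1, 1, 1), c(0.1, 0.3, 0.5), rep(0.05, 3), rep(0.1, 3))
  expect_equal(mr_weighted_median(hs1, n_boot = 50)$estimate, 0.3)
  a <- mr_weighted_median(hs1, n_boot = 200, seed = 11)
  b <- mr_weighted_median(hs1, n_boot = 200, seed = 11)
  expect_identical(a$se, b$se)
  # the bootstrap must not disturb the caller's RNG stream
  set.seed(5); x1 <- runif(1)
  set.seed(5); invisible(mr_weighted_median(hs1, n_boot = 20, seed = 3))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("gIVW reduces to IVW under identity LD and matches the GLS oracle", {
  set.seed(7)
  k <- 8
  hs <- make_hs(rnorm(k, 0.3, 0.1), rnorm(k, 0.1, 0.05),
                runif(k, 0.01, 0.05), runif(k, 0.01, 0.05))
  id <- diag(k); dimnames(id) <- list(hs$variant_id, hs$variant_id)
  gi <- mr_givw(hs, ld_matrix(id))
  iv <- mr_ivw(hs)
  expect_equal(gi$estimate, iv$estimate, tolerance = 1e-10)
  expect_equal(gi$se, iv$se, tolerance = 1e-10)
  expect_equal(gi$q_statistic, iv$q_statistic, tolerance = 1e-10)
  # random PSD correlation vs brute-force GLS
  for (s in 1:5) {
    r <- random_corr(k, seed = 200 + s)
    gi <- mr_givw(hs, ld_matrix(r))
    sigma <- outer(hs$se_out, hs$se_out) * r
    want <- oracle_gls_origin(hs$beta_exp, hs$beta_out, sigma)
    expect_equal(gi$estimate, want$estimate, tolerance = 1e-8)
    expect_equal(gi$se / gi$re_scaling, want$se, tolerance = 1e-8)
  }
})

test_that("duplicating a fully correlated instrument barely changes gIVW", {
  set.seed(8)
  k <- 5
  hs <- make_hs(rnorm(k, 0.3, 0.05), rnorm(k, 0.1, 0.03),
                runif(k, 0.01, 0.03), runif(k, 0.02, 0.04))
  r <- random_corr(k, seed = 42)
  single <- mr_givw(hs, ld_matrix(r))
  # append an exact copy of instrument 1 (r = 1 pair)
  hs2 <- pwmr:::hs_subset(hs, c(1, 1:k))
  hs2$variant_id[1] <- "rs_dup"
  r2 <- rbind(cbind(1, r[1, , drop = FALSE]), cbind(r[, 1, drop = FALSE], r))
  dimnames(r2) <- list(c("rs_dup", rownames(r)), c("rs_dup", colnames(r)))
  dup <- suppressWarnings(mr_givw(hs2, structure(r2, class = class(ld_matrix(r)))))
  expect_equal(dup$estimate, single$estimate, tolerance = 1e-6)
  # the duplicate must not manufacture precision
  expect_gte(dup$se / dup$re_scaling, 0.99 * single$se / single$re_scaling)
})

test_that("gEgger reduces to MR-Egger under identity LD and matches GLS", {
  set.seed(9)
  k <- 8
  hs <- make_hs(abs(rnorm(k, 0.3, 0.1)) + 0.05, rnorm(k, 0.1, 0.05),
                runif(k, 0.01, 0.05), runif(k, 0.01, 0.05))
  id <- diag(k); dimnames(id) <- list(hs$variant_id, hs$variant_id)
  ge <- mr_gegger(hs, ld_matrix(id))
  eg <- mr_egger(hs)
  expect_equal(ge$estimate, eg$estimate, tolerance = 1e-10)
  expect_equal(ge$intercept, eg$intercept, tolerance = 1e-10)
  expect_equal(ge$se, eg$se, tolerance = 1e-10)
  # exact-line data: slope recovered, intercept 0 under any LD
  hs_line <- make_hs(c(0.2, 0.35, 0.5, 0.65), 0.3 * c(0.2, 0.35, 0.5, 0.65),
                     rep(0.02, 4), rep(0.05, 4))
  r <- random_corr(4, seed = 77)
  gl <- mr_gegger(hs_line, ld_matrix(r))
  expect_equal(gl$estimate, 0.3, tolerance = 1e-8)
  expect_equal(gl$intercept, 0, tolerance = 1e-8)
  # random instance vs brute-force GLS with intercept (all bx > 0 so the
  # orientation step is a no-op)
  r <- random_corr(k, seed = 300)
  ge <- mr_gegger(hs, ld_matrix(r))
  sigma <- outer(hs$se_out, hs$se_out) * r
  want <- oracle_gls_intercept(hs$beta_exp, hs$beta_out, sigma)
  expect_equal(ge$estimate, want$slope, tolerance = 1e-8)
  expect_equal(ge$intercept, want$intercept, tolerance = 1e-8)
})

test_that("Cochran's Q matches the arithmetic definition", {
  hs0 <- make_hs(c(1, 1, 1), c(0.3, 0.3, 0.3), rep(0.05, 3), rep(0.1, 3))
  q0 <- cochran_q(hs0, 0.3)
  expect_equal(q0$q, 0, tolerance = 1e-20)
  expect_equal(q0$p, 1)
  # ratios 0 and 1 with se_ratio 0.5 each, estimate 0.5 -> Q = 2, df 1
  hs <- make_hs(c(1, 1), c(0, 1), c(0.05, 0.05), c(0.5, 0.5))
  q <- cochran_q(hs, 0.5)
  expect_equal(q$q, 2)
  expect_equal(q$df, 1L)
})

test_that("estimators are scale-equivariant and allele-flip invariant", {
  set.seed(12)
  k <- 6
  hs <- make_hs(rnorm(k, 0.3, 0.1), rnorm(k, 0.1, 0.05),
                runif(k, 0.01, 0.05), runif(k, 0.01, 0.05))
  r <- random_corr(k, seed = 5)
  c_mult <- 3.7
  hs_sc <- hs; hs_sc$beta_out <- c_mult * hs$beta_out
  hs_sc$se_out <- c_mult * hs$se_out
  for (fn in list(mr_ivw, mr_egger,
                  function(h) mr_givw(h, ld_matrix(r)),
                  function(h) mr_gegger(h, ld_matrix(r)))) {
    expect_equal(fn(hs_sc)$estimate, c_mult * fn(hs)$estimate,
                 tolerance = 1e-9)
    expect_equal(fn(hs_sc)$se, c_mult * fn(hs)$se, tolerance = 1e-9)
  }
  # flip one instrument's alleles (and its LD row/column signs)
  flip <- c(-1, rep(1, k - 1))
  hs_fl <- hs
  hs_fl$beta_exp <- flip * hs$beta_exp
  hs_fl$beta_out <- flip * hs$beta_out
  r_fl <- r * outer(flip, flip); dimnames(r_fl) <- dimnames(r)
  expect_equal(mr_ivw(hs_fl)$estimate, mr_ivw(hs)$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(hs_fl)$estimate, mr_egger(hs)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(hs_fl, n_boot = 50, seed = 2)$estimate,
               mr_weighted_median(hs, n_boot = 50, seed = 2)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_givw(hs_fl, ld_matrix(r_fl))$estimate,
               mr_givw(hs, ld_matrix(r))$estimate, tolerance = 1e-10)
  expect_equal(mr_gegger(hs_fl, ld_matrix(r_fl))$estimate,
               mr_gegger(hs, ld_matrix(r))$estimate, tolerance = 1e-10)
})
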