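# Two-sample MR estimators: Wald ratio, IVW, MR-Egger, weighted median,
# and the correlated-instrument generalisations gIVW and gEgger.

CI_Z <- stats::qnorm(0.975)  # 1.959964...

mr_result <- function(method, estimate, se, n_instruments,
                      intercept = NA_real_, intercept_se = NA_real_,
                      intercept_p = NA_real_,
                      q_statistic = NA_real_, q_p = NA_real_,
                      re_scaling = 1, notes = character(0)) {
  structure(list(method = method,
                 estimate = estimate, se = se,
                 ci_low = estimate - CI_Z * se,
                 ci_high = estimate + CI_Z * se,
                 p_value = z_to_p(estimate / se),
                 n_instruments = n_instruments,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_p = intercept_p,
                 q_statistic = q_statistic, q_p = q_p,
                 re_scaling = re_scaling, notes = notes),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s): estimate %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, k = %d\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$p_value,
              x$n_instruments))
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
             n_instruments = x$n_instruments, intercept = x$intercept,
             intercept_se = x$intercept_se, intercept_p = x$intercept_p,
             q_statistic = x$q_statistic, q_p = x$q_p,
             re_scaling = x$re_scaling, stringsAsFactors = FALSE)
}

# First-order Wald-ratio quantities for a harmonised set.
ratio_stats <- function(hs, second_order = FALSE) {
  if (any(hs$beta_exp == 0)) stop("beta_exp = 0: Wald ratio undefined")
  ratio <- hs$beta_out / hs$beta_exp
  se <- if (second_order) {
    sqrt(hs$se_out^2 / hs$beta_exp^2 +
           hs$beta_out^2 * hs$se_exp^2 / hs$beta_exp^4)
  } else {
    abs(hs$se_out / hs$beta_exp)
  }
  list(ratio = ratio, se = se, w = 1 / se^2)
}

#' Wald ratio (single-instrument) causal estimate
#'
#' `estimate = beta_out / beta_exp`; first-order delta-method standard
#' error `|se_out / beta_exp|` by default, with the second-order form
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)` on
#' request.
#'
#' @param hs a one-row [harmonise()]d set.
#' @param second_order use the second-order delta-method SE.
#' @return an `mr_result` with `method = "wald_ratio"`.
#' @export
mr_wald_ratio <- function(hs, second_order = FALSE) {
  if (nrow(hs) != 1) stop("wald ratio takes exactly one instrument")
  rs <- ratio_stats(hs, second_order)
  mr_result("wald_ratio", rs$ratio, rs$se, 1L)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Weighted least squares of outcome on exposure effects through the
#' origin with weights `1/se_out^2`; equivalently the inverse-variance
#' meta-analysis of first-order Wald ratios. Cochran's Q is reported and
#' the standard error is inflated by the multiplicative random-effects
#' factor `sqrt(max(1, Q/(k-1)))`.
#'
#' @param hs a [harmonise()]d set with >= 2 instruments.
#' @return an `mr_result` with `method = "ivw"`.
#' @export
mr_ivw <- function(hs) {
  k <- nrow(hs)
  if (k < 2) stop("IVW needs >= 2 instruments; use mr_wald_ratio()")
  rs <- ratio_stats(hs)
  est <- sum(rs$w * rs$ratio) / sum(rs$w)
  se_fixed <- sqrt(1 / sum(rs$w))
  q <- sum(rs$w * (rs$ratio - est)^2)
  scaling <- sqrt(max(1, q / (k - 1)))
  mr_result("ivw", est, se_fixed * scaling, k,
            q_statistic = q, q_p = stats::pchisq(q, k - 1, lower.tail = FALSE),
            re_scaling = scaling)
}

# Orient instruments so every exposure effect is positive (required for
# Egger-type fits); returns the flipped set and the sign vector applied.
orient_positive <- function(hs) {
  s <- ifelse(hs$beta_exp < 0, -1, 1)
  hs$beta_exp <- s * hs$beta_exp
  hs$beta_out <- s * hs$beta_out
  list(hs = hs, signs = s)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with a free
#' intercept (weights `1/se_out^2`), after flipping instruments to
#' positive exposure effect. The slope is the causal estimate; a nonzero
#' intercept indicates directional pleiotropy. Standard errors carry the
#' multiplicative random-effects factor `sqrt(max(1, Q/(k-2)))`.
#'
#' @param hs a [harmonise()]d set with >= 3 instruments.
#' @return an `mr_result` with `method = "egger"` and intercept fields.
#' @export
mr_egger <- function(hs) {
  k <- nrow(hs)
  if (k < 3) stop("MR-Egger needs >= 3 instruments")
  hs <- orient_positive(hs)$hs
  w <- 1 / hs$se_out^2
  X <- cbind(1, hs$beta_exp)
  XtW <- t(X * w)
  cov_fixed <- solve(XtW %*% X)
  coef <- cov_fixed %*% (XtW %*% hs$beta_out)
  resid <- hs$beta_out - X %*% coef
  q <- sum(w * resid^2)
  scaling <- sqrt(max(1, q / (k - 2)))
  se <- sqrt(diag(cov_fixed)) * scaling
  mr_result("egger", coef[2], se[2], k,
            intercept = coef[1], intercept_se = se[1],
            intercept_p = z_to_p(coef[1] / se[1]),
            q_statistic = q, q_p = stats::pchisq(q, k - 2, lower.tail = FALSE),
            re_scaling = scaling)
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  j <- which(s >= 0.5)[1]
  r[j - 1] + (r[j] - r[j - 1]) * (0.5 - s[j - 1]) / (s[j] - s[j - 1])
}

#' Weighted median estimate
#'
#' Weighted median of the first-order Wald ratios (weights
#' `1/se_ratio^2`), consistent when at least half the instrument weight is
#' valid: ratios are sorted, normalised weights cumulated, and the
#' estimate interpolated at cumulative weight 0.5. The standard error
#' comes from a seeded parametric bootstrap resampling `beta_exp` and
#' `beta_out` from their normal sampling distributions.
#'
#' @param hs a [harmonise()]d set with >= 3 instruments.
#' @param n_boot bootstrap draws.
#' @param seed integer seed for the bootstrap (RNG state is restored).
#' @return an `mr_result` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(hs, n_boot = 1000, seed = 1) {
  k <- nrow(hs)
  if (k < 3) stop("weighted median needs >= 3 instruments")
  rs <- ratio_stats(hs)
  est <- weighted_median_point(rs$ratio, rs$w)
  boot <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, hs$beta_exp, hs$se_exp)
      by <- stats::rnorm(k, hs$beta_out, hs$se_out)
      bx[bx == 0] <- .Machine$double.eps
      r <- by / bx
      se_r <- abs(hs$se_out / bx)
      weighted_median_point(r, 1 / se_r^2)
    }, numeric(1))
  })
  mr_result("weighted_median", est, stats::sd(boot), k)
}

# Outcome-effect covariance under LD, with a logged ridge-regularisation
# ladder: Sigma_ij = se_i se_j r_ij; lambda * diag added at 1e-6, escalating
# x10 to 1e-2, until the matrix inverts with acceptable conditioning.
solve_sigma <- function(se_out, r) {
  sigma <- outer(se_out, se_out) * r
  lambdas <- c(0, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2)
  for (lam in lambdas) {
    s <- sigma + lam * diag(diag(sigma), nrow = nrow(sigma))
    inv <- tryCatch({
      if (rcond(s) < 1e-12) NULL else solve(s)
    }, error = function(e) NULL)
    if (!is.null(inv)) {
      if (lam > 0) {
        warning(sprintf("LD covariance regularised with lambda = %g", lam),
                call. = FALSE)
      }
      return(list(inv = inv, lambda = lam))
    }
  }
  stop("outcome-effect covariance not invertible after maximum regularisation")
}

#' Generalised IVW (gIVW) for correlated instruments
#'
#' Generalised least squares of outcome on exposure effects through the
#' origin under the LD-induced covariance `Sigma_ij = se_out_i se_out_j
#' r_ij`: `estimate = (x' S^-1 x)^-1 x' S^-1 y`. Near-singular Sigma is
#' ridge-regularised (lambda from 1e-6 escalating tenfold to 1e-2) with a
#' logged warning. The GLS residual Q statistic drives the same
#' multiplicative random-effects scaling as [mr_ivw()]; under identity LD
#' the two coincide exactly.
#'
#' @param hs a [harmonise()]d set with >= 1 instrument.
#' @param ld an [ld_matrix()] covering the instruments (variant order is
#'   matched by id).
#' @return an `mr_result` with `method = "givw"`.
#' @export
mr_givw <- function(hs, ld) {
  k <- nrow(hs)
  if (k < 1) stop("gIVW needs >= 1 instrument")
  r <- unclass(ld_subset(ld, hs$variant_id))
  sol <- solve_sigma(hs$se_out, r)
  x <- hs$beta_exp; y <- hs$beta_out
  xsx <- as.numeric(t(x) %*% sol$inv %*% x)
  est <- as.numeric(t(x) %*% sol$inv %*% y) / xsx
  se_fixed <- sqrt(1 / xsx)
  if (k > 1) {
    resid <- y - est * x
    q <- as.numeric(t(resid) %*% sol$inv %*% resid)
    scaling <- sqrt(max(1, q / (k - 1)))
    q_p <- stats::pchisq(q, k - 1, lower.tail = FALSE)
  } else {
    q <- NA_real_; q_p <- NA_real_; scaling <- 1
  }
  mr_result("givw", est, se_fixed * scaling, k,
            q_statistic = q, q_p = q_p, re_scaling = scaling,
            notes = if (sol$lambda > 0) sprintf("ridge lambda %g", sol$lambda)
                    else character(0))
}

#' Generalised MR-Egger (gEgger) for correlated instruments
#'
#' GLS with intercept and slope under the LD-induced outcome covariance,
#' after orienting instruments to positive exposure effects (the LD
#' correlations of flipped instruments change sign accordingly). The
#' intercept test is the pleiotropy test. Reduces to [mr_egger()] under
#' identity LD.
#'
#' @param hs a [harmonise()]d set with >= 3 instruments.
#' @param ld an [ld_matrix()] covering the instruments.
#' @return an `mr_result` with `method = "gegger"` and intercept fields.
#' @export
mr_gegger <- function(hs, ld) {
  k <- nrow(hs)
  if (k < 3) stop("gEgger needs >= 3 instruments")
  r <- unclass(ld_subset(ld, hs$variant_id))
  o <- orient_positive(hs)
  hs <- o$hs
  r <- r * outer(o$signs, o$signs)
  sol <- solve_sigma(hs$se_out, r)
  X <- cbind(1, hs$beta_exp)
  cov_fixed <- solve(t(X) %*% sol$inv %*% X)
  coef <- cov_fixed %*% (t(X) %*% sol$inv %*% hs$beta_out)
  resid <- hs$beta_out - X %*% coef
  q <- as.numeric(t(resid) %*% sol$inv %*% resid)
  scaling <- sqrt(max(1, q / (k - 2)))
  se <- sqrt(diag(cov_fixed)) * scaling
  mr_result("gegger", coef[2], se[2], k,
            intercept = coef[1], intercept_se = se[1],
            intercept_p = z_to_p(coef[1] / se[1]),
            q_statistic = q, q_p = stats::pchisq(q, k - 2, lower.tail = FALSE),
            re_scaling = scaling,
            notes = if (sol$lambda > 0) sprintf("ridge lambda %g", sol$lambda)
                    else character(0))
}

#' Cochran's heterogeneity Q for Wald ratios
#'
#' `Q = sum w_i (ratio_i - estimate)^2` with first-order inverse-variance
#' weights; `df = k - 1`, p from the chi-squared distribution.
#'
#' @param hs a [harmonise()]d set with >= 2 instruments.
#' @param estimate the causal estimate the ratios are compared against.
#' @return list with `q`, `df`, `p`.
#' @export
cochran_q <- function(hs, estimate) {
  k <- nrow(hs)
  if (k < 2) stop("Cochran's Q needs >= 2 instruments")
  rs <- ratio_stats(hs)
  q <- sum(rs$w * (rs$ratio - estimate)^2)
  list(q = q, df = k - 1L,
       p = stats::pchisq(q, k - 1, lower.tail = FALSE))
}
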