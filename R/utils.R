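# Internal numerical helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-sum-exp of a numeric vector
#'
#' Stable computation of \code{log(sum(exp(x)))}. Used for all hypothesis
#' and configuration sums in the colocalisation module.
#' @param x numeric vector of log values (may contain \code{-Inf}).
#' @return scalar log of the summed exponentials.
#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; ties (or numerically crossed values)
# collapse to -Inf rather than NaN.
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Signed log-space sum: sum(signs * exp(logs)). Returns list(log=, sign=).
# Needed for the inclusion-exclusion sum over distinct three-variant
# assignments in moloc().
signed_logsumexp <- function(logs, signs) {
  stopifnot(length(logs) == length(signs))
  keep <- logs > -Inf
  logs <- logs[keep]; signs <- signs[keep]
  if (length(logs) == 0L) return(list(log = -Inf, sign = 1))
  m <- max(logs)
  s <- sum(signs * exp(logs - m))
  if (s == 0) return(list(log = -Inf, sign = 1))
  list(log = m + log(abs(s)), sign = sign(s))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded subroutines (e.g. the weighted-median bootstrap) do
# not perturb an enclosing simulation stream.
local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Derive a bounded child seed from a parent seed and a stream index.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 9973) %% 2147483629
}

z_to_p <- function(z) 2 * stats::pnorm(-abs(z))
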