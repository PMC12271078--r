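# Multiple-testing control: Benjamini-Hochberg FDR and Bonferroni FWER.

check_pvec <- function(p) {
  if (length(p) == 0) return(invisible(TRUE))
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  invisible(TRUE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Sort ascending, take `q_i = min_{j >= i} p_j * m / j`, restore input
#' order, cap at 1 (delegates to [stats::p.adjust()] with
#' `method = "BH"`).
#'
#' @param p vector of p-values in (0, 1]; empty input gives empty output.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  check_pvec(p)
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni-adjusted p-values
#'
#' `min(1, p * m)` elementwise.
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p) {
  check_pvec(p)
  stats::p.adjust(p, method = "bonferroni")
}
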