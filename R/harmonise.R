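# Harmonisation of exposure/outcome summary statistics onto a common
# effect allele.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) unname(COMPLEMENT[ea]) == oa

#' Align outcome effects to the exposure's effect allele
#'
#' Variants present in both tables are keyed by variant id. Allele pairs are
#' compared allowing for a swapped report (effect/other exchanged: outcome
#' beta negated, eaf reflected, `flipped = TRUE`) and for a strand-flipped
#' report (both alleles complemented). Palindromic variants (A/T or C/G)
#' cannot be strand-resolved from alleles alone and are oriented by
#' effect-allele-frequency agreement; when either trait's eaf lies within
#' `palindrome_eaf_window` of 0.5 the variant is dropped with reason
#' `"ambiguous palindrome"`. Incompatible allele pairs are dropped with
#' reason `"allele mismatch"`. Drops are recorded, never raised.
#'
#' @param exposure,outcome validated [summary_stats()] tables.
#' @param palindrome_eaf_window half-width of the ambiguity band around an
#'   eaf of 0.5 (default 0.08, i.e. drop when eaf is in \[0.42, 0.58\]).
#' @return A `harmonised_set`: data frame with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_exp`, `se_exp`,
#'   `p_exp`, `n_exp`, `eaf_exp`, `beta_out`, `se_out`, `p_out`, `n_out`,
#'   `eaf_out`, `flipped`; attributes `exposure_id`, `outcome_id`,
#'   `outcome_type`, and `dropped` (variant_id, reason).
#' @export
harmonise <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  e <- as.data.frame(exposure)[match(shared, exposure$variant_id), ]
  o <- as.data.frame(outcome)[match(shared, outcome$variant_id), ]

  n <- length(shared)
  keep <- logical(n); flip <- logical(n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    ea_e <- e$effect_allele[i]; oa_e <- e$other_allele[i]
    ea_o <- o$effect_allele[i]; oa_o <- o$other_allele[i]
    pal <- is_palindromic(ea_e, oa_e)
    same_pair <- setequal(c(ea_e, oa_e), c(ea_o, oa_o))
    comp_pair <- setequal(c(ea_e, oa_e),
                          unname(COMPLEMENT[c(ea_o, oa_o)]))
    if (!same_pair && !comp_pair) {
      reason[i] <- "allele mismatch"
      next
    }
    if (pal) {
      # allele letters cannot distinguish strand; orient by eaf agreement
      w <- palindrome_eaf_window
      if (abs(e$eaf[i] - 0.5) <= w || abs(o$eaf[i] - 0.5) <= w) {
        reason[i] <- "ambiguous palindrome"
        next
      }
      keep[i] <- TRUE
      flip[i] <- (e$eaf[i] - 0.5) * (o$eaf[i] - 0.5) < 0
    } else {
      aligned <- if (same_pair) ea_o == ea_e else unname(COMPLEMENT[ea_o]) == ea_e
      keep[i] <- TRUE
      flip[i] <- !aligned
    }
  }

  rows <- data.frame(
    variant_id = shared[keep],
    chrom = e$chrom[keep],
    pos = e$pos[keep],
    effect_allele = e$effect_allele[keep],
    other_allele = e$other_allele[keep],
    beta_exp = e$beta[keep], se_exp = e$se[keep], p_exp = e$pval[keep],
    n_exp = e$n[keep], eaf_exp = e$eaf[keep],
    beta_out = ifelse(flip[keep], -o$beta[keep], o$beta[keep]),
    se_out = o$se[keep], p_out = o$pval[keep], n_out = o$n[keep],
    eaf_out = ifelse(flip[keep], 1 - o$eaf[keep], o$eaf[keep]),
    flipped = flip[keep],
    stringsAsFactors = FALSE
  )
  rownames(rows) <- NULL
  dropped <- data.frame(variant_id = shared[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  structure(rows,
            exposure_id = trait_id(exposure),
            outcome_id = trait_id(outcome),
            outcome_type = trait_type(outcome),
            dropped = dropped,
            class = c("harmonised_set", "data.frame"))
}

# Subset a harmonised_set preserving attributes; optionally append drops.
hs_subset <- function(hs, idx, extra_dropped = NULL) {
  out <- as.data.frame(hs)[idx, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- attr(hs, "dropped", exact = TRUE)
  if (!is.null(extra_dropped) && nrow(extra_dropped) > 0) {
    dropped <- rbind(dropped, extra_dropped)
  }
  structure(out,
            exposure_id = attr(hs, "exposure_id", exact = TRUE),
            outcome_id = attr(hs, "outcome_id", exact = TRUE),
            outcome_type = attr(hs, "outcome_type", exact = TRUE),
            dropped = dropped,
            class = c("harmonised_set", "data.frame"))
}
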