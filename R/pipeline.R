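# End-to-end orchestration: proteome-wide MR with multiple-testing control,
# colocalisation follow-up, correlated-instrument (GMR) validation, reverse
# MR, and evidence tiering.

#' Analysis configuration
#'
#' Bundles every cutoff the pipeline applies: the strict primary
#' instrument profile (P < 5e-8, clump r2 = 0.001), the moderate
#' (P < 5e-6, r2 = 0.1) and liberal (P < 1e-4, r2 = 0.4) GMR profiles, the
#' 500 kb cis window, the MAF >= 0.05 colocalisation filter, the F >= 10
#' weak-instrument bar, FDR at 5% per outcome, the PPH4 tiers (strong >=
#' 0.80, suggestive >= 0.60) and the three-trait colocalisation priors.
#'
#' @param p_primary,clump_r2_primary strict profile.
#' @param p_moderate,clump_r2_moderate moderate profile.
#' @param p_liberal,clump_r2_liberal liberal profile.
#' @param window_kb cis-window flank in kilobases.
#' @param maf_min colocalisation MAF filter.
#' @param f_min minimum instrument F-statistic.
#' @param fdr_alpha FDR significance level (per outcome).
#' @param pph4_strong,pph4_suggestive colocalisation tier boundaries.
#' @param moloc_priors per-SNP priors for one/two/three traits.
#' @param wm_n_boot weighted-median bootstrap draws.
#' @param seed integer seed for every stochastic step.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(p_primary = 5e-8, clump_r2_primary = 0.001,
                            p_moderate = 5e-6, clump_r2_moderate = 0.1,
                            p_liberal = 1e-4, clump_r2_liberal = 0.4,
                            window_kb = 500, maf_min = 0.05, f_min = 10,
                            fdr_alpha = 0.05,
                            pph4_strong = 0.80, pph4_suggestive = 0.60,
                            moloc_priors = c(1e-4, 1e-6, 1e-7),
                            wm_n_boot = 500, seed = 1) {
  stopifnot(p_primary < p_moderate, p_moderate < p_liberal,
            p_liberal < 1, window_kb >= 0, maf_min >= 0, maf_min < 0.5,
            fdr_alpha > 0, fdr_alpha < 1,
            pph4_suggestive < pph4_strong, pph4_strong <= 1)
  structure(list(p_primary = p_primary, clump_r2_primary = clump_r2_primary,
                 p_moderate = p_moderate,
                 clump_r2_moderate = clump_r2_moderate,
                 p_liberal = p_liberal, clump_r2_liberal = clump_r2_liberal,
                 window_kb = window_kb, maf_min = maf_min, f_min = f_min,
                 fdr_alpha = fdr_alpha, pph4_strong = pph4_strong,
                 pph4_suggestive = pph4_suggestive,
                 moloc_priors = moloc_priors, wm_n_boot = wm_n_boot,
                 seed = seed),
            class = "analysis_config")
}

# Deterministic per-pair seed derived from the config seed and the pair's
# identity (not its position in the input lists, so permuting inputs
# leaves results unchanged).
pair_seed <- function(seed, exposure_id, outcome_id) {
  s <- paste0(exposure_id, "|", outcome_id)
  h <- sum(utf8ToInt(s) * seq_along(utf8ToInt(s)))
  child_seed(seed, h %% 1e6)
}

panel_for <- function(panel, exposure_id) {
  if (is.list(panel) && !is.matrix(panel)) {
    p <- panel[[exposure_id]]
    if (is.null(p)) stop("no panel for exposure ", exposure_id)
    p
  } else panel
}

# Instrument selection + harmonisation for one exposure/outcome pair under
# a (p_threshold, clump_r2) profile. Returns the filtered harmonised set
# (possibly 0 rows) plus the LD matrix over kept instruments, or a status.
select_pair_instruments <- function(exposure, outcome, panel, interval,
                                    p_threshold, clump_r2, f_min,
                                    steiger = TRUE) {
  region <- if (!is.null(interval)) {
    regional_slice(exposure, interval, maf_min = 0)
  } else exposure
  cand <- select_by_pvalue(region, p_threshold)
  # only variants typed in the panel (and polymorphic there) can be clumped
  in_panel <- cand$variant_id %in% colnames(panel)
  cand <- ss_subset(cand, which(in_panel))
  if (nrow(cand) > 0) {
    sds <- apply(panel[, cand$variant_id, drop = FALSE], 2, stats::sd)
    cand <- ss_subset(cand, which(sds > 0))
  }
  if (nrow(cand) == 0) {
    return(list(hs = NULL, ld = NULL, status = "no instruments"))
  }
  ld <- compute_ld_matrix(panel, cand$variant_id)
  clumped <- ld_clump(cand, ld, clump_r2)
  hs <- harmonise(ss_subset(exposure,
                            match(clumped$variant_id, exposure$variant_id)),
                  outcome)
  if (nrow(hs) > 0) hs <- f_filter(hs, f_min)
  if (steiger && nrow(hs) > 0) hs <- steiger_filter(hs)
  if (nrow(hs) == 0) {
    return(list(hs = hs, ld = NULL, status = "no instruments"))
  }
  list(hs = hs, ld = ld_subset(ld, hs$variant_id), status = "ok")
}

empty_pair_row <- function(exposure_id, outcome_id, status) {
  data.frame(exposure_id = exposure_id, outcome_id = outcome_id,
             status = status, method = NA_character_,
             n_instruments = 0L, estimate = NA_real_, se = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
             stringsAsFactors = FALSE)
}

# Primary MR for one pair: Wald ratio at k = 1, IVW at k >= 2.
primary_pair_mr <- function(exposure, outcome, panel, interval, config,
                            steiger = TRUE) {
  sel <- select_pair_instruments(exposure, outcome, panel, interval,
                                 config$p_primary, config$clump_r2_primary,
                                 config$f_min, steiger = steiger)
  eid <- trait_id(exposure); oid <- trait_id(outcome)
  if (sel$status != "ok") {
    return(list(row = empty_pair_row(eid, oid, sel$status),
                hs = sel$hs, ld = NULL, mr = NULL))
  }
  hs <- sel$hs
  mr <- if (nrow(hs) == 1) mr_wald_ratio(hs) else mr_ivw(hs)
  row <- cbind(data.frame(exposure_id = eid, outcome_id = oid,
                          status = "ok", stringsAsFactors = FALSE),
               as.data.frame(mr)[, c("method", "n_instruments", "estimate",
                                     "se", "ci_low", "ci_high", "p_value")])
  list(row = row, hs = hs, ld = sel$ld, mr = mr)
}

# GMR (correlated-instrument) follow-up at one profile.
gmr_pair <- function(exposure, outcome, panel, interval, config,
                     p_threshold, clump_r2, steiger = TRUE) {
  sel <- select_pair_instruments(exposure, outcome, panel, interval,
                                 p_threshold, clump_r2, config$f_min,
                                 steiger = steiger)
  if (sel$status != "ok") return(NULL)
  res <- list(givw = suppressWarnings(mr_givw(sel$hs, sel$ld)))
  if (nrow(sel$hs) >= 3) {
    res$gegger <- suppressWarnings(mr_gegger(sel$hs, sel$ld))
    res$weighted_median <- mr_weighted_median(
      sel$hs, n_boot = config$wm_n_boot,
      seed = pair_seed(config$seed, trait_id(exposure), trait_id(outcome)))
  }
  res$n_instruments <- nrow(sel$hs)
  res
}

run_mr_screen <- function(exposures, outcomes, panel, genes, config,
                          cis = TRUE, steiger = TRUE) {
  rows <- list()
  details <- list()
  for (oid_idx in seq_along(outcomes)) {
    outcome <- outcomes[[oid_idx]]
    for (eid_idx in seq_along(exposures)) {
      exposure <- exposures[[eid_idx]]
      eid <- trait_id(exposure); oid <- trait_id(outcome)
      interval <- NULL
      if (cis) {
        g <- genes[genes$gene_id == eid, , drop = FALSE]
        if (nrow(g) == 0) stop("no gene annotation for exposure ", eid)
        interval <- cis_window(g[1, ], config$window_kb)
      }
      res <- primary_pair_mr(exposure, outcome,
                             panel_for(panel, eid), interval, config,
                             steiger = steiger)
      key <- paste(eid, oid, sep = "|")
      rows[[key]] <- res$row
      details[[key]] <- list(hs = res$hs, ld = res$ld, mr = res$mr,
                             interval = interval)
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       details = details)
}

add_fdr_per_outcome <- function(table, fdr_alpha) {
  table$q_fdr <- NA_real_
  table$p_bonferroni <- NA_real_
  for (oid in unique(table$outcome_id)) {
    idx <- which(table$outcome_id == oid & !is.na(table$p_value))
    if (length(idx) > 0) {
      table$q_fdr[idx] <- bh_fdr(table$p_value[idx])
      table$p_bonferroni[idx] <- bonferroni_adjust(table$p_value[idx])
    }
  }
  table$fdr_significant <- !is.na(table$q_fdr) & table$q_fdr < fdr_alpha
  table$bonferroni_significant <-
    !is.na(table$p_bonferroni) & table$p_bonferroni < fdr_alpha
  table
}

#' Proteome-wide two-sample MR pipeline
#'
#' For every exposure-outcome pair: cis-window slice, significance filter,
#' greedy LD clumping at the strict profile, harmonisation, F-statistic
#' and Steiger filtering, then Wald ratio (one instrument) or IVW (two or
#' more). FDR and Bonferroni corrections are applied separately within
#' each outcome across exposures. FDR-significant pairs receive MR-Egger
#' and weighted median when at least three instruments are available,
#' pairwise colocalisation over the cis window, and correlated-instrument
#' GMR (gIVW, plus gEgger at three or more instruments) at the liberal and
#' moderate profiles. Evidence flags: `gmr_consistent` (liberal-profile
#' gIVW same sign as the primary estimate with p < 0.05) and `validated`
#' (FDR-significant AND colocalisation strong or suggestive AND GMR
#' consistent) — the triangulation rule for a reported association.
#'
#' @param exposures list of [summary_stats()] (e.g. protein GWAS).
#' @param outcomes list of [summary_stats()] (e.g. lipid GWAS).
#' @param panel dosage matrix, or named list of matrices keyed by exposure
#'   id.
#' @param genes gene annotation data frame (`gene_id` matching exposure
#'   trait ids, `chrom`, `start`, `end`).
#' @param config an [analysis_config()].
#' @return a `pipeline_report`: list with `table` (one row per pair),
#'   `details` (per-pair instrument sets and estimator objects) and
#'   `config`. Exposures with zero surviving instruments are reported with
#'   status `"no instruments"`, never raised.
#' @export
run_proteome_wide_mr <- function(exposures, outcomes, panel, genes, config =
                                   analysis_config()) {
  screen <- run_mr_screen(exposures, outcomes, panel, genes, config,
                          cis = TRUE)
  finalise_report(screen, exposures, outcomes, panel, config, cis = TRUE)
}

#' Reverse MR: lipid fractions as exposures, proteins as outcomes
#'
#' Identical machinery to [run_proteome_wide_mr()] without the cis-window
#' restriction (instruments are selected genome-wide from the exposure
#' table); Steiger filtering still applies.
#'
#' @inheritParams run_proteome_wide_mr
#' @return a `pipeline_report`.
#' @export
run_reverse_mr <- function(exposures, outcomes, panel,
                           config = analysis_config()) {
  screen <- run_mr_screen(exposures, outcomes, panel, genes = NULL, config,
                          cis = FALSE)
  finalise_report(screen, exposures, outcomes, panel, config, cis = FALSE)
}

finalise_report <- function(screen, exposures, outcomes, panel, config, cis) {
  table <- add_fdr_per_outcome(screen$table, config$fdr_alpha)
  table$pph4 <- NA_real_
  table$coloc_class <- NA_character_
  table$gmr_estimate <- NA_real_
  table$gmr_se <- NA_real_
  table$gmr_p <- NA_real_
  table$gmr_n_instruments <- NA_integer_
  table$gmr_consistent <- NA
  table$egger_estimate <- NA_real_
  table$egger_intercept_p <- NA_real_
  table$wm_estimate <- NA_real_
  table$validated <- FALSE

  exp_by_id <- stats::setNames(exposures,
                               vapply(exposures, trait_id, character(1)))
  out_by_id <- stats::setNames(outcomes,
                               vapply(outcomes, trait_id, character(1)))

  for (i in which(table$fdr_significant)) {
    eid <- table$exposure_id[i]; oid <- table$outcome_id[i]
    key <- paste(eid, oid, sep = "|")
    det <- screen$details[[key]]
    exposure <- exp_by_id[[eid]]; outcome <- out_by_id[[oid]]
    pnl <- panel_for(panel, eid)

    # sensitivity estimators on the primary instrument set
    if (!is.null(det$hs) && nrow(det$hs) >= 3) {
      eg <- mr_egger(det$hs)
      wm <- mr_weighted_median(det$hs, n_boot = config$wm_n_boot,
                               seed = pair_seed(config$seed, eid, oid))
      table$egger_estimate[i] <- eg$estimate
      table$egger_intercept_p[i] <- eg$intercept_p
      table$wm_estimate[i] <- wm$estimate
      screen$details[[key]]$egger <- eg
      screen$details[[key]]$weighted_median <- wm
    }

    # colocalisation over the analysis window
    cl <- tryCatch({
      s1 <- regional_slice(exposure, det$interval, config$maf_min)
      s2 <- regional_slice(outcome, det$interval, config$maf_min)
      coloc_abf(s1, s2, maf_min = config$maf_min)
    }, error = function(e) NULL)
    if (!is.null(cl)) {
      table$pph4[i] <- cl$pph["H4"]
      table$coloc_class[i] <- classify_coloc(cl$pph["H4"])
      screen$details[[key]]$coloc <- cl
    }

    # GMR at the liberal profile (moderate kept as a secondary check)
    gmr_lib <- gmr_pair(exposure, outcome, pnl, det$interval, config,
                        config$p_liberal, config$clump_r2_liberal)
    gmr_mod <- gmr_pair(exposure, outcome, pnl, det$interval, config,
                        config$p_moderate, config$clump_r2_moderate)
    screen$details[[key]]$gmr_liberal <- gmr_lib
    screen$details[[key]]$gmr_moderate <- gmr_mod
    if (!is.null(gmr_lib)) {
      g <- gmr_lib$givw
      table$gmr_estimate[i] <- g$estimate
      table$gmr_se[i] <- g$se
      table$gmr_p[i] <- g$p_value
      table$gmr_n_instruments[i] <- gmr_lib$n_instruments
      table$gmr_consistent[i] <-
        sign(g$estimate) == sign(table$estimate[i]) & g$p_value < 0.05
    }
    table$validated[i] <- isTRUE(table$fdr_significant[i]) &&
      isTRUE(table$coloc_class[i] %in% c("strong", "suggestive")) &&
      isTRUE(table$gmr_consistent[i])
  }

  structure(list(table = table, details = screen$details, config = config,
                 cis = cis),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("MR pipeline report: %d pair(s), %d FDR-significant, %d validated\n",
              nrow(x$table), sum(x$table$fdr_significant),
              sum(x$table$validated)))
  invisible(x)
}
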