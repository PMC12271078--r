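# Observational interaction regression: protein level x ancestry on a
# lipid fraction.

#' Observational protein-lipid regression with an ancestry interaction
#'
#' Ordinary least squares of a lipid fraction on protein level, a binary
#' ancestry flag, their interaction, and nuisance covariates. Continuous
#' columns (more than two distinct values) are standardised before
#' modelling. With several proteins, each is fitted in turn and the
#' interaction and protein p-values receive a Benjamini-Hochberg
#' correction across proteins.
#'
#' @param pheno a [simulate_phenotype_table()] result or any data frame.
#' @param protein column name(s) of the protein level(s).
#' @param lipid column name of the lipid fraction.
#' @param covariates character vector of covariate column names.
#' @param ancestry column name of the binary ancestry flag.
#' @param standardise standardise continuous columns before fitting
#'   (default `TRUE`); set `FALSE` when the table is already on the
#'   analysis scale.
#' @return data frame with one row per coefficient and protein: `protein`,
#'   `term`, `estimate`, `se`, `p_value`, and `q_fdr` on the protein and
#'   interaction terms. Errors on a rank-deficient design, naming the
#'   collinear columns.
#' @export
observational_interaction <- function(pheno, protein = "protein_level",
                                      lipid = "lipid_level",
                                      covariates = c("age", "sex", "bmi"),
                                      ancestry = "ancestry_flag",
                                      standardise = TRUE) {
  cols <- unique(c(protein, lipid, covariates, ancestry))
  missing_cols <- setdiff(cols, names(pheno))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(pheno)[, cols, drop = FALSE]
  n_par <- length(covariates) + 4
  if (nrow(df) <= n_par + 10) stop("too few rows for the design")
  if (standardise) {
    for (col in cols) {
      v <- df[[col]]
      if (length(unique(v)) > 2) df[[col]] <- as.vector(scale(v))
    }
  }

  fit_one <- function(p) {
    fml <- stats::reformulate(
      c(p, ancestry, paste0(p, ":", ancestry), covariates),
      response = lipid)
    fit <- stats::lm(fml, data = df)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      stop("rank-deficient design; collinear column(s): ",
           paste(names(cf)[is.na(cf)], collapse = ", "))
    }
    sm <- summary(fit)$coefficients
    data.frame(protein = p, term = rownames(sm), estimate = sm[, 1],
               se = sm[, 2], p_value = sm[, 4],
               row.names = NULL, stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(protein, fit_one))
  out$q_fdr <- NA_real_
  for (kind in c("main", "interaction")) {
    idx <- if (kind == "main") {
      which(out$term %in% protein)
    } else {
      which(grepl(":", out$term, fixed = TRUE))
    }
    if (length(idx) > 0) {
      out$q_fdr[idx] <- bh_fdr(pmax(out$p_value[idx], .Machine$double.xmin))
    }
  }
  out
}
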