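#' Full metabolome-wide association analysis
#'
#' Runs, on a processed matrix: (1) the moderated linear model for adjusted
#' log2 fold changes with BH FDR across all features jointly; (2) per-wave
#' logistic regressions pooled by fixed-effects inverse-variance
#' meta-analysis (OR per 1 log2-intensity unit), with its own BH FDR;
#' (3) the replication rubric over the per-wave logistic p-values; and
#' (4) case-only phenotype associations (LEDD, HY stage, UPDRS-III), each
#' with a BH FDR within its phenotype family.
#'
#' @param pm processed_matrix.
#' @param subjects optional subject metadata override.
#' @param replication list of replication thresholds (see
#'   [classify_replication()]).
#' @param phenotypes character subset of `c("ledd", "hy", "updrs3")` to run
#'   among cases (skipped silently if constant/absent).
#' @return data.frame with one row per feature: the MWAS summary table.
#' @export
run_mwas <- function(pm, subjects = NULL, replication = list(),
                     phenotypes = c("ledd", "hy", "updrs3")) {
  subjects <- subjects %||% pm$subjects
  mod <- fit_moderated_linear(pm, subjects)
  tab <- mod$table
  logi <- fit_logistic_per_wave(pm, subjects)
  waves <- sort(unique(subjects$wave))
  if (length(waves) != 2L)
    stopf("run_mwas expects exactly two study waves, got %d", length(waves))
  w1 <- as.character(waves[1]); w2 <- as.character(waves[2])
  tab$b_disc <- logi[[paste0("b_w", w1)]]
  tab$se_disc <- logi[[paste0("se_w", w1)]]
  tab$p_disc <- logi[[paste0("p_w", w1)]]
  tab$b_rep <- logi[[paste0("b_w", w2)]]
  tab$se_rep <- logi[[paste0("se_w", w2)]]
  tab$p_rep <- logi[[paste0("p_w", w2)]]
  meta <- meta_fixed(tab$b_disc, tab$se_disc, tab$b_rep, tab$se_rep)
  tab$b_meta <- meta$b_meta
  tab$se_meta <- meta$se_meta
  tab$or_meta <- exp(meta$b_meta)
  tab$or_ci_low <- exp(meta$b_meta - 1.96 * meta$se_meta)
  tab$or_ci_high <- exp(meta$b_meta + 1.96 * meta$se_meta)
  tab$p_meta <- meta$p_meta
  tab$fdr_meta <- bh_fdr(meta$p_meta)
  tab$single_wave <- meta$single_wave
  tab$replication_tier <- classify_replication(tab, replication)

  for (ph in phenotypes) {
    res <- tryCatch(phenotype_assoc(pm, ph, subjects), error = function(e) NULL)
    if (is.null(res)) next
    tab[[paste0(ph, "_beta")]] <- res$beta
    tab[[paste0(ph, "_p")]] <- res$p
    tab[[paste0(ph, "_fdr")]] <- res$fdr
  }
  tab
}
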