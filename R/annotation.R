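PROTON_MASS <- 1.007276

#' Default electrospray adduct rules
#'
#' Positive mode: `[M+H]+`, `[M+Na]+`, `[M+H-H2O]+`; negative mode:
#' `[M-H]-`, `[M+Cl]-`, `[M-H2O-H]-`.  By convention the HILIC column runs
#' in positive and the C18 column in negative mode.
#'
#' @return data.frame: name, mode (`pos`/`neg`), mass_shift (Da), charge.
#' @export
default_adducts <- function() {
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+H-H2O]+",
             "[M-H]-", "[M+Cl]-", "[M-H2O-H]-"),
    mode = c("pos", "pos", "pos", "neg", "neg", "neg"),
    mass_shift = c(PROTON_MASS, 22.989218, PROTON_MASS - 18.010565,
                   -PROTON_MASS, 34.969402, -18.010565 - PROTON_MASS),
    charge = rep(1L, 6),
    stringsAsFactors = FALSE)
}

#' Expected m/z of a metabolite under an adduct rule
#'
#' `m/z = (monoisotopic mass + mass shift) / charge`.
#'
#' @param monoisotopic_mass neutral monoisotopic mass in Da.
#' @param rule one row of an adduct table (list/data.frame with `mass_shift`
#'   and `charge`).
#' @return expected m/z.
#' @export
expected_mz <- function(monoisotopic_mass, rule) {
  (monoisotopic_mass + rule$mass_shift) / rule$charge
}

#' Match features to a reference library through adduct rules
#'
#' For every feature x adduct x library metabolite, the mass error is
#' `ppm = 1e6 (observed - expected)/expected`.  A tier-1 hit needs
#' `|ppm| <= ppm_tol_tier1` and a library retention time for the feature's
#' column within `rt_tol` seconds; a tier-2 hit needs only
#' `|ppm| <= ppm_tol_tier2`.  Tolerances are inclusive.  One feature may hit
#' several metabolites (all kept; downstream weighting handles ambiguity);
#' hits are sorted by |ppm error|.
#'
#' @param features data.frame with feature_id, column, mz, rt.
#' @param library data.frame with metabolite_id, name, monoisotopic_mass and
#'   optional rt_c18 / rt_hilic columns.
#' @param adducts adduct table (default [default_adducts()]); positive-mode
#'   rules apply to `hilicpos` features, negative-mode to `c18neg`.
#' @param ppm_tol_tier1,ppm_tol_tier2 mass tolerances (ppm).
#' @param rt_tol retention-time tolerance in seconds for tier 1.
#' @return data.frame of hits: feature_id, metabolite_id, adduct, ppm_error,
#'   rt_error (NA when no library RT), tier (1 = mass+RT, 2 = mass-only).
#' @export
match_features <- function(features, library, adducts = default_adducts(),
                           ppm_tol_tier1 = 5, ppm_tol_tier2 = 10,
                           rt_tol = 30) {
  if (any(library$monoisotopic_mass <= 0))
    stopf("library masses must be > 0")
  hits <- list()
  for (ai in seq_len(nrow(adducts))) {
    rule <- adducts[ai, ]
    col_type <- if (rule$mode == "pos") "hilicpos" else "c18neg"
    feats <- features[features$column == col_type, , drop = FALSE]
    if (!nrow(feats)) next
    exp_mz <- expected_mz(library$monoisotopic_mass, rule)
    rt_col <- if (col_type == "c18neg") "rt_c18" else "rt_hilic"
    lib_rt <- if (rt_col %in% names(library)) library[[rt_col]]
    else rep(NA_real_, nrow(library))
    for (fi in seq_len(nrow(feats))) {
      ppm <- 1e6 * (feats$mz[fi] - exp_mz) / exp_mz
      cand <- which(abs(ppm) <= ppm_tol_tier2)
      if (!length(cand)) next
      rt_err <- feats$rt[fi] - lib_rt[cand]
      tier1 <- abs(ppm[cand]) <= ppm_tol_tier1 &
        !is.na(rt_err) & abs(rt_err) <= rt_tol
      hits[[length(hits) + 1L]] <- data.frame(
        feature_id = feats$feature_id[fi],
        metabolite_id = library$metabolite_id[cand],
        adduct = rule$name,
        ppm_error = ppm[cand],
        rt_error = rt_err,
        tier = ifelse(tier1, 1L, 2L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(feature_id = character(0), metabolite_id = character(0),
                      adduct = character(0), ppm_error = numeric(0),
                      rt_error = numeric(0), tier = integer(0)))
  out <- do.call(rbind, hits)
  out <- out[order(abs(out$ppm_error), out$feature_id, out$metabolite_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
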