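## single logistic fit; returns c(b, se, p) for the feature term or NAs
## when the fit is flagged (non-convergence or separation-scale SE).
logistic_one <- function(y, X) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(c(NA_real_, NA_real_, NA_real_))
  R <- qr.R(fit$qr)
  cov <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(cov)) return(c(NA_real_, NA_real_, NA_real_))
  b <- fit$coefficients[2L]
  se <- sqrt(cov[2L, 2L])
  # separation / degenerate fits: absurd scale of the feature coefficient
  if (!is.finite(b) || !is.finite(se) || se > 10 || abs(b) > 15)
    return(c(NA_real_, NA_real_, NA_real_))
  c(b, se, 2 * stats::pnorm(-abs(b / se)))
}

#' Per-wave logistic regression of disease status on each feature
#'
#' Unconditional maximum-likelihood logistic fit of case status on the
#' feature (per 1 log2-intensity unit) plus covariates (age, gender,
#' ethnicity, draw-period indicator; wave omitted as it is constant within a
#' wave), separately within each study wave.  Non-converging or separating
#' fits yield a flagged row of `NA` estimates (later excluded from
#' meta-analysis), never an error.
#'
#' @param pm processed_matrix.
#' @param subjects optional subject metadata override.
#' @return data.frame: feature_id, then b, se, p per wave
#'   (`b_w1, se_w1, p_w1, b_w2, se_w2, p_w2` for waves 1 and 2).
#' @export
fit_logistic_per_wave <- function(pm, subjects = NULL) {
  values <- pm$values
  subjects <- subjects %||% pm$subjects
  subjects <- subjects[match(colnames(values), subjects$subject_id), ]
  covars <- subject_covariates(subjects)
  waves <- sort(unique(subjects$wave))
  out <- data.frame(feature_id = rownames(values), stringsAsFactors = FALSE)
  for (w in waves) {
    sel <- subjects$wave == w
    y <- covars$case[sel]
    if (length(unique(y)) < 2L)
      stopf("wave %s lacks both outcome classes", w)
    Xbase <- cbind(1, as.matrix(covars[sel, c("age_c", "male", "eth_hispanic",
                                              "eth_other", "draw_late")]))
    Xbase <- Xbase[, c(TRUE, apply(Xbase[, -1, drop = FALSE], 2,
                                   function(v) stats::var(v) > 0)),
                   drop = FALSE]
    res <- t(vapply(seq_len(nrow(values)), function(i) {
      logistic_one(y, cbind(Xbase[, 1, drop = FALSE], values[i, sel],
                            Xbase[, -1, drop = FALSE]))
    }, numeric(3)))
    out[[paste0("b_w", w)]] <- res[, 1]
    out[[paste0("se_w", w)]] <- res[, 2]
    out[[paste0("p_w", w)]] <- res[, 3]
  }
  out
}

#' Linear association between features and patient phenotypes
#'
#' Among cases only, regresses the phenotype (LEDD, HY stage or UPDRS-III)
#' on each feature plus covariates (age, gender, ethnicity, draw-period
#' indicator, wave) and reports the feature coefficient with Wald inference
#' and a BH FDR within the phenotype family.
#'
#' @param pm processed_matrix.
#' @param phenotype one of `"ledd"`, `"hy"`, `"updrs3"`.
#' @param subjects optional subject metadata override.
#' @return data.frame: feature_id, beta, se, p, fdr.
#' @export
phenotype_assoc <- function(pm, phenotype = c("ledd", "hy", "updrs3"),
                            subjects = NULL) {
  phenotype <- match.arg(phenotype)
  values <- pm$values
  subjects <- subjects %||% pm$subjects
  subjects <- subjects[match(colnames(values), subjects$subject_id), ]
  cases <- subjects$status == "case"
  y <- subjects[[phenotype]][cases]
  if (anyNA(y)) {
    keep <- !is.na(y)
    y <- y[keep]
    cases[cases] <- keep
  }
  if (length(unique(y)) < 2L) stopf("phenotype %s is constant among cases",
                                    phenotype)
  covars <- subject_covariates(subjects[cases, , drop = FALSE])
  keep_cols <- c("age_c", "male", "eth_hispanic", "eth_other", "draw_late",
                 "wave2")
  C <- cbind(1, as.matrix(covars[, keep_cols]))
  C <- C[, c(TRUE, apply(C[, -1, drop = FALSE], 2,
                         function(v) stats::var(v) > 0)), drop = FALSE]
  V <- values[, cases, drop = FALSE]
  n <- length(y)
  p_cov <- ncol(C)

  ## residualize phenotype and features on covariates, then simple slopes
  qC <- qr(C)
  y_r <- qr.resid(qC, y)
  f_r <- t(qr.resid(qC, t(V)))
  fss <- rowSums(f_r^2)
  beta <- drop(f_r %*% y_r) / fss
  df <- n - p_cov - 1
  if (df < 1) stopf("not enough cases for phenotype model")
  rss <- sum(y_r^2) - beta^2 * fss
  se <- sqrt(pmax(rss, 0) / df / fss)
  tt <- beta / se
  pv <- 2 * stats::pt(-abs(tt), df = df)
  data.frame(feature_id = rownames(values), beta = beta, se = se, p = pv,
             fdr = bh_fdr(pv), stringsAsFactors = FALSE, row.names = NULL)
}

#' Greedy age-matched subset for sensitivity analyses
#'
#' Within strata of gender and ethnicity, each case (in subject-id order) is
#' matched to the `ratio` unused controls nearest in age within
#' `max_age_diff` years; ties break toward the lower subject id.  Cases
#' without a full match are dropped.  Deterministic.
#'
#' @param subjects subject metadata data.frame.
#' @param max_age_diff maximum |age difference| in years.
#' @param ratio controls per case.
#' @return character vector of matched subject ids (cases and controls).
#' @export
match_age_controls <- function(subjects, max_age_diff = 2, ratio = 1) {
  matched <- character(0)
  for (g in sort(unique(subjects$gender))) {
    for (e in sort(unique(subjects$ethnicity))) {
      stratum <- subjects[subjects$gender == g & subjects$ethnicity == e, ]
      cases <- stratum[stratum$status == "case", ]
      ctrls <- stratum[stratum$status == "control", ]
      cases <- cases[order(cases$subject_id), ]
      ctrls <- ctrls[order(ctrls$subject_id), ]
      used <- rep(FALSE, nrow(ctrls))
      for (i in seq_len(nrow(cases))) {
        dif <- abs(ctrls$age - cases$age[i])
        dif[used | dif > max_age_diff] <- NA
        if (sum(!is.na(dif)) < ratio) next
        pick <- order(dif, ctrls$subject_id, na.last = TRUE)[seq_len(ratio)]
        if (anyNA(dif[pick])) next
        used[pick] <- TRUE
        matched <- c(matched, cases$subject_id[i], ctrls$subject_id[pick])
      }
    }
  }
  sort(matched)
}

#' Pearson correlation network of selected features
#'
#' Pairwise Pearson correlation between the selected feature rows across all
#' subjects; undirected edges where `|r| >= min_abs_r`, signed r reported,
#' no self-edges.
#'
#' @param pm processed_matrix (or plain matrix).
#' @param features character vector of feature ids (rows) to include.
#' @param min_abs_r absolute-correlation threshold (default 0.2).
#' @return data.frame edge list: feature_a, feature_b, r.
#' @export
correlation_network <- function(pm, features, min_abs_r = 0.2) {
  values <- if (inherits(pm, "processed_matrix")) pm$values else as.matrix(pm)
  sel <- values[match(features, rownames(values)), , drop = FALSE]
  if (anyNA(rownames(sel))) stopf("unknown feature ids")
  if (nrow(sel) < 2L)
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      r = numeric(0)))
  cc <- stats::cor(t(sel))
  idx <- which(upper.tri(cc) & abs(cc) >= min_abs_r, arr.ind = TRUE)
  data.frame(feature_a = rownames(cc)[idx[, 1]],
             feature_b = colnames(cc)[idx[, 2]],
             r = cc[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a correlation network
#'
#' @param edges edge list from [correlation_network()].
#' @param path_tsv TSV output path (or NULL).
#' @param path_graphml GraphML output path (or NULL).
#' @return invisibly, the igraph object.
#' @export
write_network <- function(edges, path_tsv = NULL, path_graphml = NULL) {
  if (!is.null(path_tsv)) write_tsv_file(edges, path_tsv)
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(path_graphml))
    igraph::write_graph(gr, path_graphml, format = "graphml")
  invisible(gr)
}
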