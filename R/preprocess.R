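#' Preprocessing configuration
#'
#' @param filter [filter_config()] thresholds.
#' @param detect_clusters run PC-cluster detection and, when a technical
#'   split is found, an extra batch-correction pass on the cluster
#'   indicator.
#' @param cluster_k_pcs,cluster_silhouette,cluster_min_frac parameters of
#'   [detect_technical_clusters()].
#' @param cluster_max_case_cor a detected split is only treated as
#'   technical (and corrected) when its point correlation with case status
#'   stays below this value; a case-aligned split is biology, not batch.
#' @param per_run process each LC-HRMS run independently instead of the
#'   pooled two-run table (sensitivity analysis mode).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(filter = filter_config(),
                              detect_clusters = TRUE,
                              cluster_k_pcs = 2,
                              cluster_silhouette = 0.4,
                              cluster_min_frac = 0.05,
                              cluster_max_case_cor = 0.3,
                              per_run = FALSE) {
  structure(list(filter = filter, detect_clusters = detect_clusters,
                 cluster_k_pcs = cluster_k_pcs,
                 cluster_silhouette = cluster_silhouette,
                 cluster_min_frac = cluster_min_frac,
                 cluster_max_case_cor = cluster_max_case_cor,
                 per_run = per_run),
            class = "preprocess_config")
}

## Covariate frame used throughout: case indicator, centered age, gender,
## ethnicity dummies, within-wave draw-period indicator, wave indicator.
## The draw-year indicator is a within-wave median split so that it is not
## collinear with wave.
subject_covariates <- function(subjects) {
  draw_late <- rep(0, nrow(subjects))
  for (w in unique(subjects$wave)) {
    sel <- subjects$wave == w
    draw_late[sel] <- as.numeric(subjects$draw_year[sel] >
                                   stats::median(subjects$draw_year[sel]))
  }
  data.frame(
    subject_id = subjects$subject_id,
    case = as.numeric(subjects$status == "case"),
    age_c = subjects$age - mean(subjects$age),
    male = as.numeric(subjects$gender == "male"),
    eth_hispanic = as.numeric(subjects$ethnicity == "hispanic"),
    eth_other = as.numeric(subjects$ethnicity == "other"),
    draw_late = draw_late,
    wave2 = as.numeric(subjects$wave == 2),
    stringsAsFactors = FALSE)
}

# protected design (no intercept) for a set of collapsed columns; QC columns
# get the reference level of every covariate
protected_design <- function(col_subjects, covars, include_wave = TRUE) {
  keep <- c("case", "age_c", "male", "eth_hispanic", "eth_other", "draw_late",
            if (include_wave) "wave2")
  idx <- match(col_subjects, covars$subject_id)
  mod <- as.matrix(covars[, keep, drop = FALSE])
  out <- matrix(0, length(col_subjects), length(keep),
                dimnames = list(NULL, keep))
  found <- !is.na(idx)
  out[found, ] <- mod[idx[found], , drop = FALSE]
  # drop constant columns (degenerate designs at tiny scale)
  out[, apply(out, 2, function(v) stats::var(v) > 0), drop = FALSE]
}

#' Preprocess a raw feature table
#'
#' Orchestrates, per chromatography column: quality filters -> replicate
#' collapse -> replacement of zeros by the feature's lowest nonzero detected
#' value -> log2 -> quantile normalization -> empirical-Bayes batch
#' correction (protecting disease status and covariates) -> optional
#' PC-cluster detection with a second correction pass on the cluster
#' indicator.  QC columns travel through every step alongside the study
#' columns and are reported separately.  A CV report compares per-feature QC
#' coefficients of variation before (raw linear scale) and after (linear
#' back-transform of the processed values).
#'
#' @param t raw feature_table (may contain both chromatography columns).
#' @param subjects subject metadata data.frame.
#' @param cfg [preprocess_config()].
#' @return list with `matrix` (class `processed_matrix`: `values` features x
#'   study subjects on log2 scale, `qc` features x QC columns, `features`,
#'   `subjects`, `provenance`), `cv_report` (class `cv_report`) and
#'   `filter_reports` (per column type).
#' @export
preprocess <- function(t, subjects, cfg = preprocess_config()) {
  col_types <- unique(t$features$column)
  pieces <- list()
  filter_reports <- list()
  cv_rows <- list()
  provenance <- list()
  subj_order <- NULL

  for (ct in col_types) {
    sub <- ft_subset(t, features = t$features$column == ct)
    runs <- if (cfg$per_run) sort(unique(sub$injections$run)) else NA
    run_pieces <- list()
    for (r in runs) {
      part <- if (cfg$per_run)
        ft_subset(sub, injections = sub$injections$run == r) else sub

      fil <- filter_features(part, cfg$filter)
      filter_reports[[paste0(ct, if (cfg$per_run) paste0("_run", r))]] <-
        fil$report
      collapsed <- collapse_replicates(fil$table)
      x <- collapsed$intensity

      ## QC CV before processing: raw linear QC injections of kept features
      qc_before <- part$intensity[fil$report$kept,
                                  part$injections$role == "qc", drop = FALSE]

      ## zero replacement: per-feature lowest nonzero detected value
      min_nz <- apply(x, 1, function(v) {
        nz <- v[v > 0]
        if (length(nz)) min(nz) else 1
      })
      zr <- x == 0
      x[zr] <- min_nz[row(x)[zr]]
      x <- log2(x)
      x <- quantile_normalize(x)

      covars <- subject_covariates(subjects)
      mod <- protected_design(collapsed$injections$subject_id, covars)
      x <- combat_adjust(x, collapsed$injections$batch, mod)
      steps <- list(
        list(step = "filter", params = unclass(cfg$filter)),
        list(step = "collapse_replicates", params = list(method = "median")),
        list(step = "zero_replacement", params = list(rule = "feature min nonzero")),
        list(step = "log2", params = list()),
        list(step = "quantile_normalize", params = list()),
        list(step = "combat_batch", params = list(
          n_batches = length(unique(collapsed$injections$batch)))))

      is_qc_now <- collapsed$injections$role == "qc"
      if (cfg$detect_clusters) {
        ## detect on study columns only: pooled-QC columns always separate
        ## from study samples on PCs and would trivially flag
        ind <- integer(ncol(x))
        ind[!is_qc_now] <- detect_technical_clusters(
          x[, !is_qc_now, drop = FALSE], cfg$cluster_k_pcs,
          cfg$cluster_silhouette, cfg$cluster_min_frac)
        ## a split explained by disease status is biological variation;
        ## only covariate-orthogonal splits are corrected as technical
        if (any(ind == 1L)) {
          case_col <- covars$case[match(collapsed$injections$subject_id,
                                        covars$subject_id)]
          case_col[is.na(case_col)] <- 0
          if (stats::sd(case_col) > 0 &&
              abs(stats::cor(ind, case_col)) > cfg$cluster_max_case_cor)
            ind[] <- 0L
        }
        if (any(ind == 1L)) {
          x <- combat_adjust(x, ind, mod)
          steps <- c(steps, list(list(step = "combat_technical_cluster",
                                      params = list(n_flagged = sum(ind)))))
        } else {
          steps <- c(steps, list(list(step = "cluster_check",
                                      params = list(flagged = FALSE))))
        }
      }
      provenance[[paste0(ct, if (cfg$per_run) paste0("_run", r))]] <- steps

      is_qc <- is_qc_now
      qc_after_lin <- 2^x[, is_qc, drop = FALSE]
      cv_fun <- function(mm) {
        mu <- rowMeans(mm)
        sd <- apply(mm, 1, stats::sd)
        cv <- sd / mu
        cv[mu == 0] <- NA_real_
        cv
      }
      cv_rows[[paste0(ct, if (cfg$per_run) paste0("_run", r))]] <- data.frame(
        feature_id = rownames(x),
        column = ct,
        cv_before = cv_fun(qc_before),
        cv_after = cv_fun(qc_after_lin),
        stringsAsFactors = FALSE)

      run_pieces[[as.character(r)]] <- list(
        values = x[, !is_qc, drop = FALSE],
        qc = x[, is_qc, drop = FALSE],
        features = collapsed$features,
        study_subjects = collapsed$injections$subject_id[!is_qc])
    }
    if (cfg$per_run) {
      ## per-run processing: features are shared, subjects partitioned by run
      all_subj <- unlist(lapply(run_pieces, `[[`, "study_subjects"))
      common_feat <- Reduce(intersect,
                            lapply(run_pieces, function(p) p$features$feature_id))
      vals <- do.call(cbind, lapply(run_pieces, function(p)
        p$values[common_feat, , drop = FALSE]))
      qcs <- do.call(cbind, lapply(run_pieces, function(p)
        p$qc[common_feat, , drop = FALSE]))
      feats <- run_pieces[[1]]$features
      feats <- feats[match(common_feat, feats$feature_id), , drop = FALSE]
      pieces[[ct]] <- list(values = vals, qc = qcs, features = feats,
                           study_subjects = all_subj)
    } else {
      pieces[[ct]] <- run_pieces[[1]]
    }
  }

  ## combine column types over the shared study subjects
  subj_order <- pieces[[1]]$study_subjects
  values <- do.call(rbind, lapply(pieces, function(p)
    p$values[, match(subj_order, p$study_subjects), drop = FALSE]))
  qc <- do.call(rbind, lapply(pieces, function(p) p$qc))
  features <- do.call(rbind, lapply(pieces, function(p) p$features))
  rownames(features) <- NULL
  colnames(values) <- subj_order

  cv_tab <- do.call(rbind, cv_rows)
  rownames(cv_tab) <- NULL
  summarize <- function(v) c(mean = mean(v, na.rm = TRUE),
                             median = stats::median(v, na.rm = TRUE),
                             iqr = stats::IQR(v, na.rm = TRUE))
  cv_summary <- do.call(rbind, lapply(split(cv_tab, cv_tab$column), function(d)
    data.frame(column = d$column[1],
               t(c(before = summarize(d$cv_before),
                   after = summarize(d$cv_after))))))
  rownames(cv_summary) <- NULL

  pm <- structure(list(values = values, qc = qc, features = features,
                       subjects = subjects[match(subj_order, subjects$subject_id), ],
                       provenance = provenance),
                  class = "processed_matrix")
  cvr <- structure(list(per_feature = cv_tab, summary = cv_summary),
                   class = "cv_report")
  list(matrix = pm, cv_report = cvr, filter_reports = filter_reports)
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf("processed_matrix: %d features x %d subjects (+%d QC columns)\n",
              nrow(x$values), ncol(x$values), ncol(x$qc)))
  cat(sprintf("  provenance: %s\n",
              paste(unique(unlist(lapply(x$provenance, function(p)
                vapply(p, `[[`, "", "step")))), collapse = " -> ")))
  invisible(x)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("QC coefficient of variation (linear scale), before vs after processing:\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write a processed matrix as TSV
#'
#' @param pm processed_matrix.
#' @param path output path (feature_id x subject_id table).
#' @export
write_processed_matrix <- function(pm, path) {
  out <- data.frame(feature_id = rownames(pm$values),
                    pm$values, check.names = FALSE)
  write_tsv_file(out, path)
}
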