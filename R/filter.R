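#' Feature quality-filter thresholds
#'
#' @param max_median_cv keep features whose median (across subjects)
#'   replicate CV is below this fraction.
#' @param min_replicate_pearson keep features whose mean pairwise Pearson
#'   correlation between replicate injection vectors (across subjects)
#'   exceeds this value.
#' @param min_detection_frac keep features detected (any nonzero replicate)
#'   in more than this fraction of study subjects.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_median_cv = 0.30, min_replicate_pearson = 0.9,
                          min_detection_frac = 0.50) {
  stopifnot(max_median_cv > 0, max_median_cv <= 1,
            min_detection_frac > 0, min_detection_frac <= 1,
            min_replicate_pearson >= -1, min_replicate_pearson <= 1)
  structure(list(max_median_cv = max_median_cv,
                 min_replicate_pearson = min_replicate_pearson,
                 min_detection_frac = min_detection_frac),
            class = "filter_config")
}

#' Apply replicate-quality and detection filters
#'
#' Three per-feature rules, all computed on study injections at the linear
#' intensity scale: (i) the median across subjects of the per-subject
#' replicate CV (sd/mean; a subject whose replicates are all zero is
#' skipped) must be below `max_median_cv`; (ii) the mean pairwise Pearson
#' correlation between replicate injection vectors across subjects must
#' exceed `min_replicate_pearson` (correlations undefined because one vector
#' is constant are dropped from the mean; a feature where every pair is
#' undefined passes, matching the constant-feature limit of CV 0);
#' (iii) the fraction of study subjects with at least one nonzero replicate
#' must exceed `min_detection_frac`.
#'
#' @param t feature_table with replicate injections.
#' @param cfg [filter_config()].
#' @return list with `table` (the filtered feature_table) and `report`
#'   (class `filter_report`): per-rule logical failure vectors, a partition
#'   of the dropped set by first failing rule (order: cv, pearson,
#'   detection), and a `no_replicates` flag when rules (i)-(ii) were skipped.
#' @export
filter_features <- function(t, cfg = filter_config()) {
  inj <- t$injections
  study <- inj$role == "study"
  subj <- inj$subject_id[study]
  x_study <- t$intensity[, study, drop = FALSE]
  subjects <- unique(subj)
  g <- nrow(t$features)

  rep_counts <- table(subj)
  has_reps <- any(rep_counts >= 2)

  if (has_reps) {
    subj_f <- factor(subj, levels = subjects)
    groups <- split(seq_along(subj), subj_f)
    max_rep <- max(inj$replicate_index[study])
    rep_mats <- lapply(seq_len(max_rep), function(r) {
      sel <- which(study)[inj$replicate_index[study] == r]
      m <- t$intensity[, sel, drop = FALSE]
      colnames(m) <- inj$subject_id[sel]
      m[, match(subjects, colnames(m)), drop = FALSE]
    })
    ## (i) median replicate CV (vectorized when the replicate design is
    ## balanced, which covers generator output; loop fallback otherwise)
    balanced <- length(unique(rep_counts)) == 1L && max_rep >= 2 &&
      !anyNA(do.call(cbind, lapply(rep_mats, colnames)))
    if (balanced) {
      r_n <- max_rep
      sum1 <- Reduce(`+`, rep_mats)
      sum2 <- Reduce(`+`, lapply(rep_mats, function(m) m * m))
      mu <- sum1 / r_n
      va <- pmax(0, (sum2 - r_n * mu^2) / (r_n - 1))
      cv <- sqrt(va) / mu
      cv[mu == 0] <- NA_real_   # all-zero subject: skipped
      cv_med <- apply(cv, 1, stats::median, na.rm = TRUE)
    } else {
      cv_med <- apply(x_study, 1, function(v) {
        cvs <- vapply(groups, function(ix) {
          vv <- v[ix]
          if (all(vv == 0) || length(vv) < 2) return(NA_real_)
          stats::sd(vv) / mean(vv)
        }, numeric(1))
        stats::median(cvs, na.rm = TRUE)
      })
    }
    fail_cv <- !(cv_med < cfg$max_median_cv) | is.na(cv_med)

    ## (ii) mean pairwise replicate-vector correlation across subjects
    pairs <- utils::combn(max_rep, 2)
    cors <- matrix(NA_real_, g, ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      m1 <- rep_mats[[pairs[1, k]]]
      m2 <- rep_mats[[pairs[2, k]]]
      for (i in seq_len(g)) {
        v1 <- m1[i, ]; v2 <- m2[i, ]
        if (stats::sd(v1) > 0 && stats::sd(v2) > 0)
          cors[i, k] <- stats::cor(v1, v2)
      }
    }
    mean_cor <- rowMeans(cors, na.rm = TRUE)
    fail_pearson <- !is.nan(mean_cor) & !(mean_cor > cfg$min_replicate_pearson)
  } else {
    fail_cv <- rep(FALSE, g)
    fail_pearson <- rep(FALSE, g)
  }

  ## (iii) detection frequency among study subjects
  det <- vapply(split(seq_along(subj), factor(subj, levels = subjects)),
                function(ix) colSums(t(x_study[, ix, drop = FALSE]) > 0) > 0,
                logical(g))
  if (is.null(dim(det))) det <- matrix(det, nrow = g)
  det_frac <- rowMeans(det)
  fail_detection <- !(det_frac > cfg$min_detection_frac)

  keep <- !(fail_cv | fail_pearson | fail_detection)
  first_fail <- ifelse(fail_cv, "cv",
                       ifelse(fail_pearson, "pearson",
                              ifelse(fail_detection, "detection", NA)))
  report <- structure(list(
    n_input = g,
    n_kept = sum(keep),
    kept = t$features$feature_id[keep],
    fail_cv = stats::setNames(fail_cv, t$features$feature_id),
    fail_pearson = stats::setNames(fail_pearson, t$features$feature_id),
    fail_detection = stats::setNames(fail_detection, t$features$feature_id),
    dropped_partition = table(factor(first_fail[!keep],
                                     levels = c("cv", "pearson", "detection"))),
    no_replicates = !has_reps
  ), class = "filter_report")
  if (!has_reps)
    warning("no replicate injections: CV and correlation rules skipped")
  list(table = ft_subset(t, features = keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: kept %d / %d features\n", x$n_kept, x$n_input))
  print(x$dropped_partition)
  if (x$no_replicates) cat("  (no replicates: CV/correlation rules skipped)\n")
  invisible(x)
}

# fast row-wise median of a 3-column matrix
median3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

#' Collapse replicate injections
#'
#' Each study subject's replicate injections collapse to their per-feature
#' median; QC injections collapse per (pooled profile, batch, position)
#' identically, so singleton QC injections pass through.  The resulting
#' table has one column per subject (or QC position).
#'
#' @param t feature_table.
#' @return feature_table with one injection per collapse group; collapsed QC
#'   columns are named `<subject>_B<batch>_P<position>`.
#' @export
collapse_replicates <- function(t) {
  inj <- t$injections
  key <- ifelse(inj$role == "study", inj$subject_id,
                sprintf("%s_B%02d_P%d", inj$subject_id, inj$batch,
                        inj$replicate_index))
  keys <- unique(key)
  groups <- split(seq_len(nrow(inj)), factor(key, levels = keys))
  x <- t$intensity
  out <- matrix(0, nrow(x), length(groups),
                dimnames = list(rownames(x), keys))
  new_inj <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    ix <- groups[[k]]
    out[, k] <- if (length(ix) == 1L) x[, ix]
    else if (length(ix) == 3L) median3(x[, ix[1]], x[, ix[2]], x[, ix[3]])
    else apply(x[, ix, drop = FALSE], 1, stats::median)
    first <- inj[ix[1], ]
    first$injection_id <- keys[k]
    first$replicate_index <- 1L
    first$order <- min(inj$order[ix])
    new_inj[[k]] <- first
  }
  feature_table(t$features, do.call(rbind, new_inj), out)
}
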