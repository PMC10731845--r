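#' Alignment tolerances for cross-run feature matching
#'
#' @param mz_rel_tol relative m/z tolerance (inclusive).
#' @param rt_tol_c18,rt_tol_hilic retention-time tolerance in seconds
#'   (inclusive) for the C18 and HILIC columns.
#' @return An `align_config` list.
#' @export
align_config <- function(mz_rel_tol = 1e-05, rt_tol_c18 = 37.016,
                         rt_tol_hilic = 38.246) {
  stopifnot(mz_rel_tol > 0, rt_tol_c18 > 0, rt_tol_hilic > 0)
  structure(list(mz_rel_tol = mz_rel_tol, rt_tol_c18 = rt_tol_c18,
                 rt_tol_hilic = rt_tol_hilic), class = "align_config")
}

#' Align feature tables from two LC-HRMS runs
#'
#' Greedy one-to-one matching of features between two runs of the same
#' chromatography column.  A pair is a candidate when its relative m/z
#' difference (to the mean m/z) is at most `mz_rel_tol` and its RT
#' difference at most the column's RT tolerance, both inclusive.  Candidates
#' are accepted in ascending order of a combined normalized distance
#' (Euclidean norm of the two tolerance-scaled differences), ties broken by
#' feature id.  Matched features merge to the mean m/z / RT and carry both
#' runs' injections; unmatched features carry intensity 0 for the other
#' run's injections.
#'
#' @param a,b feature_table objects (single, identical column type).
#' @param cfg [align_config()].
#' @return A merged feature_table whose injections are `a`'s followed by
#'   `b`'s.  The features data.frame gains a `matched` logical column.
#' @export
align_runs <- function(a, b, cfg = align_config()) {
  col_a <- unique(a$features$column)
  col_b <- unique(b$features$column)
  if (length(col_a) != 1L || length(col_b) != 1L || col_a != col_b)
    stopf("align_runs requires single, identical column types (got %s vs %s)",
          paste(col_a, collapse = "/"), paste(col_b, collapse = "/"))
  rt_tol <- if (col_a == "c18neg") cfg$rt_tol_c18 else cfg$rt_tol_hilic

  fa <- a$features
  fb <- b$features
  ob <- order(fb$mz)
  fb_mz <- fb$mz[ob]
  cand <- vector("list", nrow(fa))
  for (i in seq_len(nrow(fa))) {
    # widest window any mean-mz candidate can fall in
    w <- fa$mz[i] * cfg$mz_rel_tol * 1.000001 * 2
    lo <- findInterval(fa$mz[i] - w, fb_mz) + 1L
    hi <- findInterval(fa$mz[i] + w, fb_mz)
    if (hi < lo) next
    j <- ob[lo:hi]
    dmz_rel <- abs(fb$mz[j] - fa$mz[i]) / ((fb$mz[j] + fa$mz[i]) / 2)
    drt <- abs(fb$rt[j] - fa$rt[i])
    ok <- dmz_rel <= cfg$mz_rel_tol & drt <= rt_tol
    if (!any(ok)) next
    j <- j[ok]
    cand[[i]] <- data.frame(
      ia = i, ib = j,
      dist = sqrt((dmz_rel[ok] / cfg$mz_rel_tol)^2 + (drt[ok] / rt_tol)^2))
  }
  cand <- do.call(rbind, cand)
  match_a <- rep(NA_integer_, nrow(fa))
  match_b <- rep(NA_integer_, nrow(fb))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$dist, fa$feature_id[cand$ia],
                       fb$feature_id[cand$ib]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand$ia[k]; j <- cand$ib[k]
      if (is.na(match_a[i]) && is.na(match_b[j])) {
        match_a[i] <- j
        match_b[j] <- i
      }
    }
  }

  na <- ncol(a$intensity)
  nb <- ncol(b$intensity)
  matched_i <- which(!is.na(match_a))
  rows <- list()
  feats <- list()
  for (i in seq_len(nrow(fa))) {
    j <- match_a[i]
    if (!is.na(j)) {
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = fa$feature_id[i], column = col_a,
        mz = (fa$mz[i] + fb$mz[j]) / 2, rt = (fa$rt[i] + fb$rt[j]) / 2,
        matched = TRUE, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- c(a$intensity[i, ], b$intensity[j, ])
    } else {
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = fa$feature_id[i], column = col_a,
        mz = fa$mz[i], rt = fa$rt[i], matched = FALSE,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- c(a$intensity[i, ], numeric(nb))
    }
  }
  for (j in which(is.na(match_b))) {
    feats[[length(feats) + 1L]] <- data.frame(
      feature_id = fb$feature_id[j], column = col_a,
      mz = fb$mz[j], rt = fb$rt[j], matched = FALSE,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- c(numeric(na), b$intensity[j, ])
  }
  features <- do.call(rbind, feats)
  if (anyDuplicated(features$feature_id)) {
    features$feature_id <- make.unique(features$feature_id, sep = "_run")
  }
  injections <- rbind(a$injections, b$injections)
  feature_table(features, injections, do.call(rbind, rows))
}
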