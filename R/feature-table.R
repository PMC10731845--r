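#' Feature table container
#'
#' An untargeted LC-HRMS feature table: a set of features (identified by m/z
#' and retention time on a given chromatography column) crossed with
#' injections.  Intensities are nonnegative raw (linear-scale) values with 0
#' meaning "not detected".
#'
#' @param features data.frame with columns `feature_id`, `column`
#'   (`"c18neg"` or `"hilicpos"`), `mz` (Da, > 0) and `rt` (seconds, >= 0).
#' @param injections data.frame with columns `injection_id`, `subject_id`,
#'   `role` (`"study"` or `"qc"`), `replicate_index`, `batch`, `run`, `order`.
#' @param intensity numeric matrix, `nrow(features)` x `nrow(injections)`,
#'   nonnegative, no `NA`.
#'
#' @return An object of class `feature_table` with elements `features`,
#'   `injections` and `intensity` (dimnames set to feature and injection ids).
#' @export
feature_table <- function(features, injections, intensity) {
  required_f <- c("feature_id", "column", "mz", "rt")
  required_i <- c("injection_id", "subject_id", "role", "replicate_index",
                  "batch", "run", "order")
  if (!all(required_f %in% names(features)))
    stopf("features must have columns: %s", paste(required_f, collapse = ", "))
  if (!all(required_i %in% names(injections)))
    stopf("injections must have columns: %s", paste(required_i, collapse = ", "))
  if (anyDuplicated(injections$injection_id))
    stopf("injection ids must be unique")
  if (anyDuplicated(features$feature_id))
    stopf("feature ids must be unique")
  if (any(features$mz <= 0)) stopf("all mz must be > 0")
  if (any(features$rt < 0)) stopf("all rt must be >= 0")
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != nrow(features) || ncol(intensity) != nrow(injections))
    stopf("intensity must be %d x %d", nrow(features), nrow(injections))
  if (anyNA(intensity)) stopf("intensity must not contain NA")
  if (any(intensity < 0)) stopf("intensity must be nonnegative")
  dimnames(intensity) <- list(features$feature_id, injections$injection_id)
  structure(list(features = as.data.frame(features, stringsAsFactors = FALSE),
                 injections = as.data.frame(injections, stringsAsFactors = FALSE),
                 intensity = intensity),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d injections\n",
              nrow(x$features), nrow(x$injections)))
  cat(sprintf("  columns: %s\n",
              paste(sprintf("%s (%d)", names(table(x$features$column)),
                            as.integer(table(x$features$column))),
                    collapse = ", ")))
  tab <- table(x$injections$role)
  cat(sprintf("  injections: %s\n",
              paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Subset a feature table
#'
#' @param x feature_table.
#' @param features logical/integer/character index into features.
#' @param injections logical/integer/character index into injections.
#' @return feature_table restricted to the selected rows/columns.
#' @export
ft_subset <- function(x, features = NULL, injections = NULL) {
  fi <- seq_len(nrow(x$features))
  ii <- seq_len(nrow(x$injections))
  if (!is.null(features)) {
    fi <- if (is.character(features)) match(features, x$features$feature_id) else fi[features]
  }
  if (!is.null(injections)) {
    ii <- if (is.character(injections)) match(injections, x$injections$injection_id) else ii[injections]
  }
  feature_table(x$features[fi, , drop = FALSE],
                x$injections[ii, , drop = FALSE],
                x$intensity[fi, ii, drop = FALSE])
}

#' Read / write feature tables as TSV
#'
#' The on-disk format is two tab-separated files: the intensity file has
#' columns `feature_id`, `column`, `mz`, `rt_seconds`, then one column per
#' injection id; the injection metadata file has columns `injection_id`,
#' `subject_id`, `role`, `replicate_index`, `batch`, `run`, `order`.
#'
#' @param path path of the intensity TSV.
#' @param meta_path path of the injection metadata TSV.
#' @return `read_feature_table` returns a `feature_table`;
#'   `write_feature_table` returns `path` invisibly.
#' @export
read_feature_table <- function(path, meta_path) {
  tab <- read_tsv_file(path)
  meta <- read_tsv_file(meta_path)
  lead <- c("feature_id", "column", "mz", "rt_seconds")
  inj_cols <- setdiff(names(tab), lead)
  features <- data.frame(feature_id = tab$feature_id, column = tab$column,
                         mz = tab$mz, rt = tab$rt_seconds,
                         stringsAsFactors = FALSE)
  meta <- meta[match(inj_cols, meta$injection_id), , drop = FALSE]
  if (anyNA(meta$injection_id))
    stopf("metadata is missing injections present in the intensity table")
  feature_table(features, meta, as.matrix(tab[, inj_cols, drop = FALSE]))
}

#' @rdname read_feature_table
#' @param x feature_table to write.
#' @export
write_feature_table <- function(x, path, meta_path) {
  out <- data.frame(feature_id = x$features$feature_id,
                    column = x$features$column,
                    mz = x$features$mz,
                    rt_seconds = x$features$rt,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(x$intensity, check.names = FALSE))
  write_tsv_file(out, path)
  write_tsv_file(x$injections, meta_path)
  invisible(path)
}

#' Read / write subject metadata TSV
#'
#' Subject-level table with columns `subject_id`, `wave`, `status`
#' (`"case"`/`"control"`), `age`, `gender`, `ethnicity`, `smoking`,
#' `draw_year`, `ledd`, `hy`, `updrs3`.
#'
#' @param path file path.
#' @return data.frame of subjects.
#' @export
read_subjects <- function(path) read_tsv_file(path)

#' @rdname read_subjects
#' @param x subject data.frame.
#' @export
write_subjects <- function(x, path) write_tsv_file(x, path)
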