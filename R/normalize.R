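#' Quantile normalization
#'
#' Classical column-quantile normalization: each column's sorted values are
#' replaced by the across-column mean of sorted values (the reference
#' distribution); tied values receive the mean of the reference values at
#' the positions they jointly occupy, so rank order within each column is
#' preserved and all output columns share one multiset of values.  The
#' operation is idempotent.
#'
#' @param m numeric matrix (features x samples), no NA.
#' @return matrix of the same dimension and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stopf("quantile_normalize: NA values not supported")
  if (ncol(m) < 1L || nrow(m) < 1L) return(m)
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    v <- m[o, j]
    grp <- cumsum(c(TRUE, diff(v) != 0))
    out[o, j] <- stats::ave(ref, grp, FUN = mean)
  }
  out
}

#' Detect a technical sample cluster on principal components
#'
#' PCA on column vectors (features centered), followed by 2-means on the
#' top `k_pcs` scores with deterministic farthest-pair seeding.  A split is
#' only flagged when the mean silhouette width is at least
#' `silhouette_min` and the minor cluster holds at least `min_frac` of the
#' columns; otherwise an all-zero indicator is returned.  Fully
#' deterministic: repeated calls give identical output.
#'
#' @param m numeric matrix (features x samples).
#' @param k_pcs number of leading principal components to cluster on.
#' @param silhouette_min minimum mean silhouette width to flag a split.
#' @param min_frac minimum relative size of the minor cluster.
#' @return integer vector (one per column): 1 for members of the minor
#'   (outlying) cluster, else 0.
#' @export
detect_technical_clusters <- function(m, k_pcs = 2, silhouette_min = 0.4,
                                      min_frac = 0.05) {
  n <- ncol(m)
  zero <- stats::setNames(integer(n), colnames(m))
  if (n < 4L) return(zero)
  centered <- m - rowMeans(m)
  pc <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE,
                      rank. = k_pcs)
  scores <- pc$x[, seq_len(min(k_pcs, ncol(pc$x))), drop = FALSE]

  d <- as.matrix(stats::dist(scores))
  # farthest-pair seeding
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  centers <- scores[c(far[1], far[2]), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (iter in seq_len(100)) {
    d1 <- rowSums((scores - matrix(centers[1, ], n, ncol(scores),
                                   byrow = TRUE))^2)
    d2 <- rowSums((scores - matrix(centers[2, ], n, ncol(scores),
                                   byrow = TRUE))^2)
    assign_new <- ifelse(d2 < d1, 2L, 1L)
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    if (length(unique(assign_new)) < 2L) break
    centers <- rbind(colMeans(scores[assign_new == 1L, , drop = FALSE]),
                     colMeans(scores[assign_new == 2L, , drop = FALSE]))
  }
  cl <- assign_old
  if (length(unique(cl)) < 2L) return(zero)

  # mean silhouette width for the 2-cluster split
  sil <- vapply(seq_len(n), function(i) {
    own <- cl == cl[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- mean(d[i, cl != cl[i]])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))

  sizes <- table(cl)
  minor <- as.integer(names(sizes)[which.min(sizes)])
  if (mean(sil) >= silhouette_min && min(sizes) >= min_frac * n) {
    stats::setNames(as.integer(cl == minor), colnames(m))
  } else zero
}
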