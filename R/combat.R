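#' Parametric empirical-Bayes batch correction
#'
#' Location/scale batch adjustment in the ComBat family.  Per feature, a
#' linear model with batch indicators plus protected covariates is fitted;
#' data are standardized by the batch-free mean and pooled variance; additive
#' (gamma) and multiplicative (delta^2) batch effects are estimated per
#' batch and shrunk toward batch-level priors (normal prior on gamma,
#' inverse-gamma on delta^2, hyperparameters by method of moments, posteriors
#' by the standard iterative conditional-means solution); the standardized
#' data are adjusted and back-transformed.  Protected-covariate effects
#' (e.g. the case-control contrast) are restored unchanged, so the
#' correction cannot absorb them.
#'
#' @param m numeric matrix, features x samples.
#' @param batch batch label per column (factor or vector).
#' @param mod protected covariate design matrix (samples x covariates,
#'   WITHOUT intercept; the batch indicators span the intercept), or `NULL`.
#' @return adjusted matrix of the same dimension.  With a single batch the
#'   input is returned unchanged.
#' @export
combat_adjust <- function(m, batch, mod = NULL) {
  m <- as.matrix(m)
  batch <- factor(batch)
  if (length(batch) != ncol(m))
    stopf("batch must have one label per column")
  if (nlevels(batch) == 1L) return(m)
  sizes <- table(batch)
  if (any(sizes < 2L))
    stopf("singleton batch(es): %s",
          paste(names(sizes)[sizes < 2L], collapse = ", "))

  n_batch <- nlevels(batch)
  n_array <- ncol(m)
  batchmod <- stats::model.matrix(~ -1 + batch)
  design <- if (is.null(mod)) batchmod else cbind(batchmod, as.matrix(mod))
  if (qr(design)$rank < ncol(design))
    stopf("batch and protected covariates are confounded (design not full rank)")

  ## feature-wise least squares for all features at once
  beta_hat <- solve(crossprod(design), crossprod(design, t(m)))
  grand_mean <- crossprod(as.numeric(sizes) / n_array,
                          beta_hat[seq_len(n_batch), , drop = FALSE])
  resid <- m - t(design %*% beta_hat)
  var_pooled <- drop(resid^2 %*% rep(1 / n_array, n_array))  # ML pooled

  stand_mean <- matrix(grand_mean, nrow(m), n_array)
  if (!is.null(mod)) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% beta_hat)
  }
  s_data <- (m - stand_mean) / sqrt(var_pooled)

  batches <- lapply(levels(batch), function(b) which(batch == b))
  gamma_hat <- t(vapply(batches, function(ix)
    rowMeans(s_data[, ix, drop = FALSE]), numeric(nrow(m))))
  delta_hat <- t(vapply(batches, function(ix)
    apply(s_data[, ix, drop = FALSE], 1, stats::var), numeric(nrow(m))))

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  a_prior <- apply(delta_hat, 1, function(dd) {
    mm <- mean(dd); s2 <- stats::var(dd); (2 * s2 + mm^2) / s2
  })
  b_prior <- apply(delta_hat, 1, function(dd) {
    mm <- mean(dd); s2 <- stats::var(dd); (mm * s2 + mm^3) / s2
  })

  gamma_star <- matrix(0, n_batch, nrow(m))
  delta_star <- matrix(0, n_batch, nrow(m))
  for (i in seq_len(n_batch)) {
    ix <- batches[[i]]
    sol <- combat_it_sol(s_data[, ix, drop = FALSE], gamma_hat[i, ],
                         delta_hat[i, ], gamma_bar[i], t2[i],
                         a_prior[i], b_prior[i])
    gamma_star[i, ] <- sol$g_new
    delta_star[i, ] <- sol$d_new
  }

  bayesdata <- s_data
  for (i in seq_len(n_batch)) {
    ix <- batches[[i]]
    bayesdata[, ix] <- (s_data[, ix, drop = FALSE] - gamma_star[i, ]) /
      sqrt(delta_star[i, ])
  }
  bayesdata * sqrt(var_pooled) + stand_mean
}

# iterative conditional-means solution for the EB batch parameters
combat_it_sol <- function(sdat, g_hat, d_hat, g_bar, t2, a, b,
                          conv = 1e-4) {
  n <- rowSums(!is.na(sdat))
  g_old <- g_hat
  d_old <- d_hat
  change <- 1
  count <- 0
  while (change > conv) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((sdat - g_new)^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / abs(g_old),
                  abs(d_new - d_old) / d_old, na.rm = TRUE)
    g_old <- g_new
    d_old <- d_new
    count <- count + 1
    if (count > 1000) break
  }
  list(g_new = g_new, d_new = d_new)
}
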