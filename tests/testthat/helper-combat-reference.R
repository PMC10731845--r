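# Independent reference implementation of the parametric empirical-Bayes
# location/scale batch adjustment, written as a plain per-feature loop
# directly from the published algorithm (standardize; per-batch gamma/delta;
# moment-matched normal / inverse-gamma priors; iterative conditional-means
# posteriors; adjust and back-transform).  Deliberately naive and slow; used
# only as the oracle for combat_adjust().

combat_reference <- function(m, batch, mod = NULL) {
  batch <- factor(batch)
  levs <- levels(batch)
  nb <- length(levs)
  n <- ncol(m)
  G <- nrow(m)
  Z <- sapply(levs, function(b) as.numeric(batch == b))   # n x nb
  D <- if (is.null(mod)) Z else cbind(Z, mod)

  # per-feature OLS; pooled (ML) variance; batch-free standardization
  beta <- matrix(0, G, ncol(D))
  for (g in seq_len(G)) beta[g, ] <- solve(t(D) %*% D, t(D) %*% m[g, ])
  nb_frac <- as.numeric(table(batch)[levs]) / n
  alpha <- drop(beta[, seq_len(nb), drop = FALSE] %*% nb_frac)
  varp <- numeric(G)
  for (g in seq_len(G)) varp[g] <- mean((m[g, ] - D %*% beta[g, ])^2)
  stand <- matrix(0, G, n)
  for (g in seq_len(G)) {
    mu <- rep(alpha[g], n)
    if (!is.null(mod))
      mu <- mu + drop(as.matrix(mod) %*% beta[g, -(seq_len(nb))])
    stand[g, ] <- (m[g, ] - mu) / sqrt(varp[g])
  }

  gamma_hat <- matrix(0, nb, G); delta_hat <- matrix(0, nb, G)
  for (i in seq_len(nb)) {
    ix <- which(batch == levs[i])
    for (g in seq_len(G)) {
      gamma_hat[i, g] <- mean(stand[g, ix])
      delta_hat[i, g] <- var(stand[g, ix])
    }
  }

  adj <- stand
  for (i in seq_len(nb)) {
    ix <- which(batch == levs[i])
    ni <- length(ix)
    gbar <- mean(gamma_hat[i, ])
    t2 <- var(gamma_hat[i, ])
    dm <- mean(delta_hat[i, ]); ds <- var(delta_hat[i, ])
    a <- (2 * ds + dm^2) / ds
    b <- (dm * ds + dm^3) / ds
    g_old <- gamma_hat[i, ]; d_old <- delta_hat[i, ]
    repeat {
      g_new <- (t2 * ni * gamma_hat[i, ] + d_old * gbar) / (t2 * ni + d_old)
      s2 <- numeric(G)
      for (g in seq_len(G)) s2[g] <- sum((stand[g, ix] - g_new[g])^2)
      d_new <- (0.5 * s2 + b) / (ni / 2 + a - 1)
      ch <- max(abs(g_new - g_old) / abs(g_old), abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (ch < 1e-4) break
    }
    for (g in seq_len(G)) {
      mu <- rep(alpha[g], ni)
      if (!is.null(mod))
        mu <- mu + drop(as.matrix(mod)[ix, , drop = FALSE] %*%
                          beta[g, -(seq_len(nb))])
      adj[g, ix] <- (stand[g, ix] - g_old[g]) / sqrt(d_old[g]) *
        sqrt(varp[g]) + mu
    }
  }
  dimnames(adj) <- dimnames(m)
  adj
}
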