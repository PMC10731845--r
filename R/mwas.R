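#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjustment: for sorted p-values, `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, returned in the input order.  `NA` entries
#' are ignored (they do not count toward `m`) and stay `NA`.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  o <- order(pv)
  q <- pv[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out[ok[o]] <- pmin(q, 1)
  out
}

## Inverse of the trigamma function by Newton iteration on 1/trigamma
## (monotone convex parametrization), as used for the method-of-moments fit
## of the variance prior.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

## Method-of-moments fit of the scaled-inverse-chi-square variance prior:
## matches mean and variance of log s^2 via digamma/trigamma identities.
## Returns d0 (prior df, possibly Inf) and s0_sq (prior variance).
fit_variance_prior <- function(s_sq, df) {
  ok <- s_sq > 0 & df > 0
  s_sq_f <- s_sq[ok]
  df_f <- if (length(df) == 1L) rep(df, length(s_sq_f)) else df[ok]
  z <- log(s_sq_f)
  e <- z - digamma(df_f / 2) + log(df_f / 2)
  e_bar <- mean(e)
  n <- length(e)
  evar <- sum((e - e_bar)^2) / (n - 1) - mean(trigamma(df_f / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(e_bar)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated linear-model differential abundance fit
#'
#' Per feature, least squares of log2 intensity on the case indicator plus
#' covariates (age, gender, ethnicity, draw-period indicator, wave).  The
#' per-feature residual variances are shrunk toward a common prior fitted by
#' the closed-form method of moments on log variances
#' (digamma/trigamma matching); the moderated t statistic uses the posterior
#' variance `s2_post = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` on `d0 + d_g`
#' degrees of freedom.  With `d0 = Inf` (all variances equal) the common
#' variance is used; with a forced `d0 = 0` the fit reduces to ordinary
#' per-feature OLS t-tests.
#'
#' @param pm processed_matrix (or plain features x subjects matrix).
#' @param subjects subject metadata (needed when `pm` is a plain matrix or
#'   to rebuild covariates).
#' @param d0_override optionally force the prior degrees of freedom
#'   (`0` = no moderation; `Inf` = common variance).
#' @param include_wave include the wave indicator among covariates.
#' @return list with `table` (data.frame: feature_id, log2fc, ci_low,
#'   ci_high, moderated_t, p_limma, fdr_limma) and `moderation`
#'   (d0, s0_sq, s_g_sq, d_g).
#' @export
fit_moderated_linear <- function(pm, subjects = NULL, d0_override = NULL,
                                 include_wave = TRUE) {
  if (inherits(pm, "processed_matrix")) {
    values <- pm$values
    subjects <- subjects %||% pm$subjects
  } else values <- as.matrix(pm)
  subjects <- subjects[match(colnames(values), subjects$subject_id), ]
  covars <- subject_covariates(subjects)
  keep <- c("case", "age_c", "male", "eth_hispanic", "eth_other", "draw_late",
            if (include_wave) "wave2")
  X <- cbind(intercept = 1, as.matrix(covars[, keep]))
  X <- X[, c(TRUE, apply(X[, -1, drop = FALSE], 2,
                         function(v) stats::var(v) > 0)), drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stopf("covariate design is not full rank")
  n <- nrow(X)
  p <- ncol(X)
  df_resid <- n - p
  if (df_resid < 1) stopf("zero residual degrees of freedom")

  fit <- stats::lm.fit(X, t(values))
  coefs <- t(fit$coefficients)
  resid <- t(fit$residuals)
  s_sq <- rowSums(resid^2) / df_resid
  xtx_inv <- chol2inv(qr.R(qrX))
  unit_var <- xtx_inv[which(colnames(X) == "case"),
                      which(colnames(X) == "case")]

  prior <- fit_variance_prior(s_sq, df_resid)
  d0 <- d0_override %||% prior$d0
  if (is.finite(d0) && d0 > 0) {
    s2_post <- (d0 * prior$s0_sq + df_resid * s_sq) / (d0 + df_resid)
  } else if (is.infinite(d0)) {
    s2_post <- rep(prior$s0_sq, length(s_sq))
  } else {
    s2_post <- s_sq
  }
  df_total <- df_resid + d0
  b <- coefs[, "case"]
  se_mod <- sqrt(unit_var * s2_post)
  tt <- b / se_mod
  pval <- 2 * stats::pt(-abs(tt), df = df_total)
  crit <- stats::qt(0.975, df = df_total)
  tab <- data.frame(feature_id = rownames(values),
                    log2fc = b,
                    ci_low = b - crit * se_mod,
                    ci_high = b + crit * se_mod,
                    moderated_t = tt,
                    p_limma = pval,
                    fdr_limma = bh_fdr(pval),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab,
       moderation = list(d0 = prior$d0, s0_sq = prior$s0_sq,
                         s_g_sq = s_sq, d_g = df_resid))
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' `w_i = 1/se_i^2`; pooled estimate is the weight-averaged coefficient,
#' pooled SE is `(sum w_i)^(-1/2)`, p from the normal Wald test.  A missing
#' wave (NA estimate) returns the available wave's estimate flagged
#' `single_wave`.
#'
#' @param b1,se1 estimate and standard error of study 1.
#' @param b2,se2 estimate and standard error of study 2 (vectors allowed).
#' @return data.frame: b_meta, se_meta, p_meta, single_wave.
#' @export
meta_fixed <- function(b1, se1, b2, se2) {
  n <- max(length(b1), length(b2))
  b1 <- rep_len(b1, n); se1 <- rep_len(se1, n)
  b2 <- rep_len(b2, n); se2 <- rep_len(se2, n)
  if (any(se1 <= 0, na.rm = TRUE) || any(se2 <= 0, na.rm = TRUE))
    stopf("standard errors must be positive")
  m1 <- is.na(b1) | is.na(se1)
  m2 <- is.na(b2) | is.na(se2)
  w1 <- ifelse(m1, 0, 1 / se1^2)
  w2 <- ifelse(m2, 0, 1 / se2^2)
  wsum <- w1 + w2
  b_meta <- ifelse(wsum > 0,
                   (ifelse(m1, 0, w1 * b1) + ifelse(m2, 0, w2 * b2)) / wsum,
                   NA_real_)
  se_meta <- ifelse(wsum > 0, 1 / sqrt(wsum), NA_real_)
  p_meta <- 2 * stats::pnorm(-abs(b_meta / se_meta))
  data.frame(b_meta = b_meta, se_meta = se_meta, p_meta = p_meta,
             single_wave = xor(m1, m2))
}

#' Classify replication across discovery and replication waves
#'
#' A feature replicates when both waves' p-values pass `per_wave_p_max`,
#' the per-wave estimates agree in direction, and the adjusted |log2FC|
#' reaches the tier threshold: tier `"replicated_fc25"` at 0.25 and
#' `"replicated_fc50"` at 0.50; otherwise `"not_replicated"`.
#'
#' @param rows data.frame with columns p_disc, p_rep, b_disc, b_rep, log2fc.
#' @param cfg list with per_wave_p_max (default 0.05), log2fc_tier1 (0.25),
#'   log2fc_tier2 (0.50).
#' @return character vector of tier labels.
#' @export
classify_replication <- function(rows, cfg = list()) {
  p_max <- cfg$per_wave_p_max %||% 0.05
  t1 <- cfg$log2fc_tier1 %||% 0.25
  t2 <- cfg$log2fc_tier2 %||% 0.50
  stopifnot(t2 > t1)
  both_p <- !is.na(rows$p_disc) & !is.na(rows$p_rep) &
    rows$p_disc < p_max & rows$p_rep < p_max
  same_dir <- sign(rows$b_disc) == sign(rows$b_rep)
  base <- both_p & same_dir & !is.na(same_dir)
  ifelse(base & abs(rows$log2fc) >= t2, "replicated_fc50",
         ifelse(base & abs(rows$log2fc) >= t1, "replicated_fc25",
                "not_replicated"))
}
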