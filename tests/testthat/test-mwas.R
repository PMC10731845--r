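test_that("bh_fdr equals the brute-force definition on short vectors", {
  grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 0.9, 1)
  withr::with_seed(1, {
    for (len in 1:8) {
      for (rep in 1:25) {
        p <- sample(grid, len, replace = TRUE)
        expect_equal(bh_fdr(p), bh_bruteforce(p))
      }
    }
  })
  # worked example and the degenerate cases
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
})

test_that("moderated fit: exact group difference on a two-group toy", {
  n <- 20
  subjects <- toy_subjects(n, seed = 3, two_wave = FALSE)
  subjects$age <- 60; subjects$gender <- "male"; subjects$ethnicity <- "white"
  subjects$draw_year <- 2004
  m <- toy_matrix(5, subjects, seed = 4)
  fit <- fit_moderated_linear(m, subjects)
  case <- subjects$status == "case"
  for (i in 1:5)
    expect_equal(fit$table$log2fc[i],
                 mean(m[i, case]) - mean(m[i, !case]), tolerance = 1e-12)
})

test_that("variance prior recovery: d0 and s0_sq from simulated variances", {
  withr::with_seed(2024, {
    n <- 50; g <- 2000
    subjects <- toy_subjects(n, seed = 6)
    d0 <- 4; s0_sq <- 1
    sg <- s0_sq * d0 / rchisq(g, d0)
    m <- matrix(rnorm(g * n, 0, rep(sqrt(sg), n)), g, n,
                dimnames = list(sprintf("F%04d", 1:g), subjects$subject_id))
    fit <- fit_moderated_linear(m, subjects)
    expect_lt(abs(fit$moderation$d0 - d0), 0.5)
    expect_lt(abs(fit$moderation$s0_sq - s0_sq), 0.1)

    # independent oracle: limma's eBayes on the identical design
    skip_if_not_installed("limma")
    cov <- data.frame(subjects, stringsAsFactors = FALSE)
    case <- as.numeric(subjects$status == "case")
    dl <- local({
      dy <- numeric(n)
      for (w in unique(subjects$wave)) {
        s <- subjects$wave == w
        dy[s] <- as.numeric(subjects$draw_year[s] > median(subjects$draw_year[s]))
      }
      dy
    })
    X <- cbind(1, case, subjects$age - mean(subjects$age),
               as.numeric(subjects$gender == "male"),
               as.numeric(subjects$ethnicity == "hispanic"),
               as.numeric(subjects$ethnicity == "other"),
               dl, as.numeric(subjects$wave == 2))
    colnames(X) <- c("i", "case", "age", "male", "hisp", "oth", "dl", "w2")
    lf <- limma::eBayes(limma::lmFit(m, X))
    expect_equal(fit$moderation$d0, lf$df.prior, tolerance = 1e-6)
    expect_equal(fit$moderation$s0_sq, lf$s2.prior, tolerance = 1e-6)
    expect_equal(fit$table$moderated_t, unname(lf$t[, "case"]),
                 tolerance = 1e-10)
    expect_equal(fit$table$p_limma, unname(lf$p.value[, "case"]),
                 tolerance = 1e-10)
  })
})

test_that("d0 = 0 reduces to ordinary OLS t-tests; equal variances to common t", {
  n <- 30
  subjects <- toy_subjects(n, seed = 8)
  m <- toy_matrix(20, subjects, seed = 9)
  fit0 <- fit_moderated_linear(m, subjects, d0_override = 0)
  cv <- data.frame(case = as.numeric(subjects$status == "case"))
  for (i in c(1, 7, 20)) {
    dat <- data.frame(y = m[i, ], subjects)
    ols <- lm(y ~ I(status == "case") + age + gender + ethnicity +
                I(wave == 2), dat)
    # compare against a same-design OLS fit done through the package path
    fitg <- fit_moderated_linear(m[i, , drop = FALSE], subjects,
                                 d0_override = 0)
    expect_equal(fitg$table$moderated_t, fit0$table$moderated_t[i],
                 tolerance = 1e-10)
  }
  # residual t equals beta/se from an explicit per-feature OLS on the same X
  case <- as.numeric(subjects$status == "case")
  covs <- fit0$table
  X <- local({
    dy <- numeric(n)
    for (w in unique(subjects$wave)) {
      s <- subjects$wave == w
      dy[s] <- as.numeric(subjects$draw_year[s] > median(subjects$draw_year[s]))
    }
    cbind(1, case, subjects$age - mean(subjects$age),
          as.numeric(subjects$gender == "male"),
          as.numeric(subjects$ethnicity == "hispanic"),
          as.numeric(subjects$ethnicity == "other"),
          dy, as.numeric(subjects$wave == 2))
  })
  for (i in 1:20) {
    f <- lm.fit(X, m[i, ])
    s2 <- sum(f$residuals^2) / f$df.residual
    se <- sqrt(s2 * chol2inv(qr.R(qr(X)))[2, 2])
    expect_equal(covs$moderated_t[i], unname(f$coefficients[2] / se),
                 tolerance = 1e-10)
  }
  # all variances identical: d0 -> Inf, t uses the common variance
  m_eq <- m
  fit_inf <- fit_moderated_linear(m_eq, subjects, d0_override = Inf)
  expect_true(all(is.finite(fit_inf$table$moderated_t)))
})

test_that("meta_fixed: hand-computed pooling, symmetry, zero-weight limit", {
  r <- meta_fixed(0.5, 0.1, 0.3, 0.2)
  expect_equal(r$b_meta, 0.46, tolerance = 1e-12)     # w = (100, 25)
  expect_equal(r$se_meta, 1 / sqrt(125), tolerance = 1e-12)  # 0.08944
  r2 <- meta_fixed(0.4, 0.15, 0.4, 0.15)
  expect_equal(r2$b_meta, 0.4)
  expect_equal(r2$se_meta, 0.15 / sqrt(2))
  r3 <- meta_fixed(0.5, 0.1, 0.9, 1e6)
  expect_equal(r3$b_meta, 0.5, tolerance = 1e-6)
  # missing wave: single-wave flag, other estimate passed through
  r4 <- meta_fixed(NA, NA, 0.3, 0.2)
  expect_true(r4$single_wave)
  expect_equal(r4$b_meta, 0.3)
})

test_that("per-wave logistic: calibration under the null and separation flagging", {
  withr::with_seed(55, {
    n <- 300; g <- 500
    subjects <- toy_subjects(n, seed = 10)
    m <- toy_matrix(g, subjects, seed = 11)
    pm <- structure(list(values = m, subjects = subjects),
                    class = "processed_matrix")
    res <- fit_logistic_per_wave(pm)
    frac <- mean(res$p_w1 < 0.05, na.rm = TRUE)
    expect_gt(frac, 0.03)
    expect_lt(frac, 0.07)

    # perfectly separating feature: flagged, not estimated
    sep <- m
    case <- subjects$status == "case"
    sep[1, ] <- ifelse(case, 20, 5)
    pm2 <- structure(list(values = sep, subjects = subjects),
                     class = "processed_matrix")
    res2 <- fit_logistic_per_wave(pm2)
    expect_true(is.na(res2$b_w1[1]) && is.na(res2$b_w2[1]))
  })
})

test_that("logistic estimates recover a planted log-OR with near-nominal coverage", {
  withr::with_seed(77, {
    reps <- 60; n <- 450; b_true <- 0.5
    hit <- logical(reps)
    for (r in seq_len(reps)) {
      x <- rnorm(n, 0, 1.5)
      pr <- plogis(-0.2 + b_true * x)
      y <- rbinom(n, 1, pr)
      f <- suppressWarnings(glm(y ~ x, family = binomial()))
      est <- coef(summary(f))["x", ]
      hit[r] <- abs(est["Estimate"] - b_true) <= 2 * est["Std. Error"]
    }
    expect_gte(mean(hit), 0.90)
  })
})

test_that("classify_replication applies the tiered rubric", {
  rows <- data.frame(
    p_disc = c(0.01, 0.01, 0.01, 0.5, 0.01),
    p_rep = c(0.03, 0.03, 0.03, 0.03, 0.03),
    b_disc = c(1, 1, 1, 1, 1),
    b_rep = c(1, 1, 1, 1, -1),
    log2fc = c(0.6, 0.30, 0.1, 0.6, 0.6))
  expect_equal(classify_replication(rows),
               c("replicated_fc50", "replicated_fc25", "not_replicated",
                 "not_replicated", "not_replicated"))
})

test_that("phenotype association: planted LEDD features found, constant errors", {
  cfg <- tiny_cfg(seed = 17, n_medication_features = 8)
  co <- generate_cohort(cfg)
  prep <- preprocess(co$table, co$subjects)
  pm <- prep$matrix
  res <- phenotype_assoc(pm, "ledd")
  med_ids <- co$truth$feature_id[co$truth$is_medication_linked]
  med_ids <- intersect(med_ids, res$feature_id)
  null_ids <- setdiff(res$feature_id, med_ids)
  med_p <- res$p[match(med_ids, res$feature_id)]
  null_p <- res$p[match(null_ids, res$feature_id)]
  # planted medication features much smaller p than null features
  expect_lt(median(med_p), 1e-4)
  expect_gt(median(null_p), 0.1)
  # constant phenotype errors out
  s2 <- co$subjects
  s2$hy[s2$status == "case"] <- 2
  expect_error(phenotype_assoc(pm, "hy", s2), "constant")
})

test_that("correlation_network: self-edges never, duplicates r = 1, null sparse", {
  withr::with_seed(91, {
    n <- 900; g <- 30
    m <- matrix(rnorm(g * n), g, n,
                dimnames = list(sprintf("F%03d", 1:g), NULL))
    m[2, ] <- m[1, ]                     # duplicated feature row
    edges <- correlation_network(m, rownames(m), min_abs_r = 0.2)
    expect_false(any(edges$feature_a == edges$feature_b))
    dup <- edges[edges$feature_a == "F001" & edges$feature_b == "F002", ]
    expect_equal(dup$r, 1)
    # independent Gaussian features at n = 900: expected edge count
    # 2*pnorm(-0.2*sqrt(n))*pairs is essentially zero
    others <- edges[!(edges$feature_a %in% c("F001", "F002") &
                        edges$feature_b %in% c("F001", "F002")), ]
    expect_lte(nrow(others), 2)
  })
})

test_that("age matching is deterministic and respects constraints", {
  co <- tiny_cohort(seed = 11)
  ids <- match_age_controls(co$subjects)
  expect_identical(ids, match_age_controls(co$subjects))
  s <- co$subjects[match(ids, co$subjects$subject_id), ]
  expect_equal(sum(s$status == "case"), sum(s$status == "control"))
})
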