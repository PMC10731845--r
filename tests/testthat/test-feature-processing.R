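make_run_table <- function(g = 8, n_subj = 3, column = "c18neg", run = 1L,
                           mz = NULL, rt = NULL, seed = 1) {
  n_inj <- n_subj * 2
  m <- withr::with_seed(seed, matrix(runif(g * n_inj, 50, 150), g, n_inj))
  if (is.null(mz)) mz <- seq(100, 400, length.out = g)
  if (is.null(rt)) rt <- seq(60, 200, length.out = g)
  features <- data.frame(feature_id = sprintf("R%d_F%02d", run, seq_len(g)),
                         column = column, mz = mz, rt = rt)
  injections <- data.frame(
    injection_id = sprintf("R%d_I%02d", run, seq_len(n_inj)),
    subject_id = rep(sprintf("R%d_S%02d", run, seq_len(n_subj)), each = 2),
    role = "study", replicate_index = rep(1:2, n_subj),
    batch = run, run = run, order = seq_len(n_inj))
  feature_table(features, injections, m)
}

test_that("align_runs: identity, inclusive boundaries, distance resolution", {
  a <- make_run_table(seed = 1)
  b <- make_run_table(seed = 2, run = 2L)
  merged <- align_runs(a, b)
  # identical coordinates: every feature matches one-to-one
  expect_equal(sum(merged$features$matched), nrow(a$features))
  expect_equal(nrow(merged$features), nrow(a$features))
  expect_equal(ncol(merged$intensity),
               ncol(a$intensity) + ncol(b$intensity))

  # m/z boundary: relative difference exactly 1e-05 is matched (inclusive)
  a1 <- make_run_table(g = 1, n_subj = 1, mz = 200.000, rt = 100)
  b1 <- make_run_table(g = 1, n_subj = 1, run = 2L, mz = 200.002, rt = 100)
  m1 <- align_runs(a1, b1)
  expect_true(all(m1$features$matched))

  # RT beyond the C18 tolerance: 40 s > 37.016 s stays unmatched
  b2 <- make_run_table(g = 1, n_subj = 1, run = 2L, mz = 200.000, rt = 140)
  a2 <- make_run_table(g = 1, n_subj = 1, mz = 200.000, rt = 100)
  m2 <- align_runs(a2, b2)
  expect_false(any(m2$features$matched))
  expect_equal(nrow(m2$features), 2L)
  # unmatched features carry zeros for the other run's injections
  expect_true(all(m2$intensity[1, m2$injections$run == 2] == 0))

  # mixed column types rejected
  bh <- make_run_table(column = "hilicpos", run = 2L)
  expect_error(align_runs(a, bh), "column types")
})

test_that("filter_features applies the three rules and reports a partition", {
  # 4 features x 5 subjects x triplicate: constant / noisy / undetected / good
  n_subj <- 5
  base <- matrix(100, 4, n_subj * 3)
  base[2, ] <- rep(c(60, 100, 140), n_subj)         # within-subject CV 40/100
  base[3, ] <- 0; base[3, 1:3] <- c(5, 5, 5)        # detected in 1/5 subjects
  base[4, ] <- rep(c(90, 100, 110), n_subj) +
    rep(seq(0, 400, length.out = n_subj), each = 3) # good: CV 10%, correlated
  ft <- toy_feature_table(base)
  res <- filter_features(ft)
  kept <- res$table$features$feature_id
  expect_setequal(kept, c("c18neg_T001", "c18neg_T004"))
  expect_true(res$report$fail_cv[["c18neg_T002"]])
  expect_true(res$report$fail_detection[["c18neg_T003"]])
  # partition property: dropped features counted exactly once
  expect_equal(sum(res$report$dropped_partition),
               res$report$n_input - res$report$n_kept)

  # worked CV example: sd(90,100,110) = 10 -> subject CV 10%
  expect_equal(sd(c(90, 100, 110)) / mean(c(90, 100, 110)), 0.1)

  # detection exactly at 40% of subjects -> dropped (threshold is strict >)
  m5 <- matrix(rep(c(90, 100, 110), 5), 1, 15)
  m5[1, 7:15] <- 0
  ft5 <- toy_feature_table(m5)
  res5 <- filter_features(ft5)
  expect_equal(res5$report$n_kept, 0L)
  expect_true(res5$report$fail_detection[[1]])
})

test_that("filter_features without replicates warns and skips CV rules", {
  m <- withr::with_seed(4, matrix(runif(6 * 4, 10, 100), 6, 4))
  ft <- toy_feature_table(m, n_reps = 1)
  expect_warning(res <- filter_features(ft), "no replicate")
  expect_true(res$report$no_replicates)
  expect_equal(res$report$n_kept, 6L)
})

test_that("collapse_replicates takes per-subject medians", {
  m <- matrix(c(1, 2, 3,  0, 0, 5,  7, 7, 7), 3, 3, byrow = TRUE)
  ft <- toy_feature_table(m, n_reps = 3)
  col <- collapse_replicates(ft)
  expect_equal(ncol(col$intensity), 1L)
  expect_equal(unname(col$intensity[, 1]), c(2, 0, 7))
  # single replicate: identity
  ft1 <- toy_feature_table(matrix(c(4, 9), 2, 1), n_reps = 1)
  expect_equal(unname(collapse_replicates(ft1)$intensity[, 1]), c(4, 9))
})

test_that("quantile_normalize: worked example, fixed point, idempotence", {
  m <- cbind(c(1, 3), c(2, 4))
  expect_equal(quantile_normalize(m), cbind(c(1.5, 3.5), c(1.5, 3.5)))
  # identical columns are a fixed point
  m2 <- cbind(c(5, 1, 9), c(5, 1, 9))
  expect_equal(quantile_normalize(m2), m2)
  # output columns share one multiset; idempotent to 1e-12
  m3 <- withr::with_seed(9, matrix(rnorm(60), 10, 6))
  q <- quantile_normalize(m3)
  for (j in 2:ncol(q)) expect_equal(sort(q[, 1]), sort(q[, j]))
  expect_equal(quantile_normalize(q), q, tolerance = 1e-12)
  # ties receive the mean of their would-be quantile values
  mt <- cbind(c(1, 1, 10), c(2, 4, 6))
  qt <- quantile_normalize(mt)
  ref <- rowMeans(cbind(sort(mt[, 1]), sort(mt[, 2])))
  expect_equal(qt[1, 1], mean(ref[1:2]))
  expect_equal(qt[2, 1], mean(ref[1:2]))
})

test_that("combat_adjust: identity on single batch, errors on singletons", {
  m <- toy_matrix(10, toy_subjects(12))
  expect_identical(combat_adjust(m, rep(1, 12)), m)
  expect_error(combat_adjust(m, c(rep(1, 11), 2)), "singleton")
})

test_that("combat_adjust removes planted shifts and matches the reference oracle", {
  withr::with_seed(21, {
    g <- 10; n <- 20
    m <- matrix(rnorm(g * n, 10), g, n)
    batch <- rep(1:2, each = n / 2)
    mod <- cbind(case = rep(c(0, 1), n / 2))
    shifted <- m + outer(rep(1, g), (batch == 2) * 1.5)
    mine <- combat_adjust(shifted, batch, mod)
    oracle <- combat_reference(shifted, batch, mod)
    expect_lt(max(abs(mine - oracle)), 1e-6)
  })
})

test_that("combat_adjust: planted +2 batch shift removed, case effect kept", {
  ## at the cohort's column count (~900) the EB weight on the observed
  ## batch effect is large and the planted shift is removed almost fully;
  ## at much smaller n a uniform shift leaves irreducible shrinkage noise
  withr::with_seed(33, {
    g <- 40; n <- 900
    case <- rep(c(0, 1), n / 2)
    beta <- rep(c(0, 0.8), length.out = g)
    m <- matrix(rnorm(g * n, 12, 1), g, n) + beta %o% case
    batch <- rep(1:2, each = n / 2)
    shifted <- m + matrix(2 * (batch == 2), g, n, byrow = TRUE)
    adj <- combat_adjust(shifted, batch, mod = cbind(case = case))
    batch_diff <- apply(adj, 1, function(v)
      mean(v[batch == 2]) - mean(v[batch == 1]))
    expect_lt(mean(abs(batch_diff)), 0.05)
    expect_lt(max(abs(batch_diff)), 0.1)
    beta_before <- apply(m, 1, function(v) coef(lm(v ~ case))[2])
    beta_after <- apply(adj, 1, function(v) coef(lm(v ~ case))[2])
    expect_lt(max(abs(beta_before - beta_after)), 0.02)
  })
})

test_that("detect_technical_clusters finds planted splits and stays quiet on null", {
  withr::with_seed(14, {
    n <- 60; g <- 50
    base <- matrix(rnorm(g * n), g, n)
    plant <- seq_len(n) <= 0.3 * n
    m <- base + matrix(3 * plant, g, n, byrow = TRUE)
    ind <- detect_technical_clusters(m)
    expect_identical(unname(ind), as.integer(plant))   # adjusted Rand = 1
    # homogeneous data: no flag
    expect_true(all(detect_technical_clusters(base) == 0L))
    # deterministic
    expect_identical(detect_technical_clusters(m), ind)
  })
})

test_that("preprocess: zero replacement rule, provenance, QC CV reduction", {
  co <- tiny_cohort(seed = 11)
  res <- preprocess(co$table, co$subjects)
  pm <- res$matrix
  expect_true(all(is.finite(pm$values)))
  expect_gt(length(pm$provenance), 0)
  steps <- vapply(pm$provenance[[1]], `[[`, "", "step")
  expect_equal(steps[1:6], c("filter", "collapse_replicates",
                             "zero_replacement", "log2",
                             "quantile_normalize", "combat_batch"))
  # QC CVs drop after processing (nonzero batch_sd in the generator)
  s <- res$cv_report$summary
  expect_true(all(s$after.mean < s$before.mean))

  # explicit zero-replacement check on a hand-built table
  m <- matrix(c(0, 12.5, 40, 25, 30, 50), 1, 6)
  ft <- toy_feature_table(m, n_reps = 3)
  col <- collapse_replicates(ft)
  x <- col$intensity
  min_nz <- min(x[x > 0])
  expect_equal(min_nz, 12.5)
})
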