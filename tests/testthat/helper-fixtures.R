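# shared small-scale fixtures, generated once per test run

tiny_cfg <- function(seed = 11, ...) {
  cohort_config_test(seed = seed, ...)
}

# cached tiny cohort (deterministic; reused across test files)
tiny_cohort <- local({
  cache <- new.env()
  function(seed = 11, ...) {
    key <- paste(seed, paste(deparse(substitute(list(...))), collapse = ""),
                 sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_cohort(tiny_cfg(seed = seed, ...))
    cache[[key]]
  }
})

# plain subject frame for direct model tests (no cohort machinery)
toy_subjects <- function(n, seed = 1, two_wave = TRUE) {
  withr::with_seed(seed, data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    wave = if (two_wave) rep(1:2, length.out = n) else rep(1L, n),
    status = sample(rep(c("case", "control"), length.out = n)),
    age = round(stats::runif(n, 40, 85)),
    gender = sample(c("male", "female"), n, TRUE),
    ethnicity = sample(c("white", "hispanic", "other"), n, TRUE),
    smoking = "never",
    draw_year = sample(2000:2018, n, TRUE),
    ledd = 0, hy = NA_real_, updrs3 = NA_real_,
    stringsAsFactors = FALSE))
}

toy_matrix <- function(g, subjects, seed = 2, sd = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(g * nrow(subjects), 12, sd), g, nrow(subjects))
    dimnames(m) <- list(sprintf("F%04d", seq_len(g)), subjects$subject_id)
    m
  })
}

# minimal hand-built feature table: g features, subjects x r replicates
toy_feature_table <- function(intensity, n_reps = 3, column = "c18neg",
                              mz = NULL, rt = NULL) {
  g <- nrow(intensity)
  n_inj <- ncol(intensity)
  n_subj <- n_inj / n_reps
  stopifnot(n_subj == floor(n_subj))
  if (is.null(mz)) mz <- seq(100, 500, length.out = g)
  if (is.null(rt)) rt <- seq(30, 300, length.out = g)
  features <- data.frame(
    feature_id = sprintf("%s_T%03d", column, seq_len(g)),
    column = column, mz = mz, rt = rt)
  injections <- data.frame(
    injection_id = sprintf("I%03d", seq_len(n_inj)),
    subject_id = rep(sprintf("S%03d", seq_len(n_subj)), each = n_reps),
    role = "study",
    replicate_index = rep(seq_len(n_reps), n_subj),
    batch = 1L, run = 1L, order = seq_len(n_inj))
  feature_table(features, injections, intensity)
}
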