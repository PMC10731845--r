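#' Synthetic cohort configuration
#'
#' Parameters of the synthetic two-wave case-control metabolomics cohort.
#' Defaults emulate a community-based Parkinson's disease study design: two
#' independent waves (discovery 282 cases / 185 controls; replication 360
#' cases / 90 controls), two LC-HRMS runs, injection batches of 40 subjects
#' analyzed in triplicate with periodic pooled-QC injections, feature-level
#' batch / run / drift artifacts, a fraction of features carrying planted
#' case-control effects, medication-dose-linked features (active in cases
#' only), and age-correlated features.
#'
#' @param n_cases_wave1,n_controls_wave1 wave-1 (discovery) sample sizes.
#' @param n_cases_wave2,n_controls_wave2 wave-2 (replication) sample sizes.
#' @param batch_size subjects per analytical batch.
#' @param n_batches number of batches; `NULL` derives the minimum needed.
#' @param n_runs number of LC-HRMS runs; batches are split evenly across runs.
#' @param n_replicate_injections technical replicate injections per subject.
#' @param qc_per_batch pooled-QC injections per batch.
#' @param n_features_per_column features simulated on each chromatography
#'   column (`c18neg`, `hilicpos`).
#' @param frac_true_effects fraction of features with a nonzero planted
#'   case-control log2 fold change.
#' @param effect_log2fc_range absolute-magnitude interval the planted
#'   |log2FC| is drawn from (sign random).
#' @param n_medication_features features whose intensity scales with
#'   levodopa-equivalent daily dose (LEDD) in cases.
#' @param n_age_features features with an age slope.
#' @param n_junk_cv_features features with replicate noise engineered to fail
#'   a 30% replicate-CV filter.
#' @param batch_sd,run_sd SD (log2 scale) of per-feature batch and run
#'   offsets.
#' @param drift_slope SD of the per-feature within-run drift coefficient
#'   (log2 units over a full run).
#' @param residual_sd subject-level biological residual SD (log2 scale).
#' @param replicate_cv target linear-scale coefficient of variation between
#'   replicate injections of one extract.
#' @param junk_cv replicate CV used for junk features.
#' @param lod_quantile per-feature detection-limit quantile; linear
#'   intensities below it are recorded as 0 (not detected).
#' @param frac_mapped fraction of features assigned a reference metabolite
#'   identity (used by the annotation / pathway generators).
#' @param age_case_shift mean age difference (years), cases minus controls.
#' @param male_prob_case,male_prob_control probability of male gender.
#' @param external_n total sample size of the simulated external study.
#' @param external_rho correlation between the external study's log2FC and
#'   the internal planted log2FC.
#' @param external_noise_sd SD of the external log2FC noise component.
#' @param seed integer seed; the same configuration and seed reproduce every
#'   output exactly.
#'
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_cases_wave1 = 282, n_controls_wave1 = 185,
                          n_cases_wave2 = 360, n_controls_wave2 = 90,
                          batch_size = 40, n_batches = NULL, n_runs = 2,
                          n_replicate_injections = 3, qc_per_batch = 3,
                          n_features_per_column = 2000,
                          frac_true_effects = 0.05,
                          effect_log2fc_range = c(0.25, 2),
                          n_medication_features = 20,
                          n_age_features = 30,
                          n_junk_cv_features = 25,
                          batch_sd = 0.5, run_sd = 0.3, drift_slope = 0.2,
                          residual_sd = 1.0, replicate_cv = 0.10,
                          junk_cv = 0.60,
                          lod_quantile = 0.05,
                          frac_mapped = 0.35,
                          age_case_shift = 4,
                          male_prob_case = 0.62, male_prob_control = 0.48,
                          external_n = 460, external_rho = 0.8,
                          external_noise_sd = 0.2,
                          seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_cases_wave1", "n_controls_wave1", "n_cases_wave2",
              "n_controls_wave2", "batch_size", "n_runs",
              "n_replicate_injections", "qc_per_batch",
              "n_features_per_column", "n_medication_features",
              "n_age_features", "n_junk_cv_features", "external_n")
  for (nm in counts) if (!is_count(cfg[[nm]])) stopf("%s must be a count", nm)
  for (nm in c("frac_true_effects", "lod_quantile", "frac_mapped")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) stopf("%s must be in [0, 1]", nm)
  }
  for (nm in c("batch_sd", "run_sd", "residual_sd", "replicate_cv", "junk_cv"))
    if (cfg[[nm]] < 0 || (nm %in% c("replicate_cv") && cfg[[nm]] <= 0))
      stopf("%s must be positive", nm)
  if (length(effect_log2fc_range) != 2L || any(effect_log2fc_range < 0) ||
      diff(effect_log2fc_range) < 0)
    stopf("effect_log2fc_range must be an increasing nonnegative interval")
  n_subj <- n_cases_wave1 + n_controls_wave1 + n_cases_wave2 + n_controls_wave2
  if (!is.null(n_batches) && n_batches * batch_size < n_subj)
    stopf("config rejected: %d batches x %d slots cannot hold %d subjects",
          n_batches, batch_size, n_subj)
  structure(cfg, class = "cohort_config")
}

#' Test-scale cohort configuration
#'
#' A down-scaled configuration (about 200 features, 120 subjects) whose full
#' generation completes in well under a minute; all structural properties of
#' the full-scale design are retained.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
cohort_config_test <- function(...) {
  defaults <- list(n_cases_wave1 = 40, n_controls_wave1 = 25,
                   n_cases_wave2 = 40, n_controls_wave2 = 15,
                   batch_size = 20, n_features_per_column = 100,
                   n_medication_features = 5, n_age_features = 6,
                   n_junk_cv_features = 6)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# replicate-noise SD on the log2 scale giving a target linear-scale CV
# under the lognormal replicate model
log2_sd_for_cv <- function(cv) sqrt(log(1 + cv^2)) / log(2)

simulate_subjects <- function(cfg) {
  n <- c(cfg$n_cases_wave1, cfg$n_controls_wave1,
         cfg$n_cases_wave2, cfg$n_controls_wave2)
  wave <- rep(c(1L, 1L, 2L, 2L), n)
  status <- rep(c("case", "control", "case", "control"), n)
  ns <- sum(n)
  subject_id <- sprintf("S%04d", seq_len(ns))
  is_case <- status == "case"
  age <- round(stats::rnorm(ns, mean = ifelse(is_case, 63 + cfg$age_case_shift, 63),
                            sd = 9))
  age <- pmin(pmax(age, 35), 92)
  gender <- ifelse(stats::runif(ns) <
                     ifelse(is_case, cfg$male_prob_case, cfg$male_prob_control),
                   "male", "female")
  eth_p_case <- c(white = 0.55, hispanic = 0.35, other = 0.10)
  eth_p_ctrl <- c(white = 0.65, hispanic = 0.25, other = 0.10)
  ethnicity <- vapply(seq_len(ns), function(i) {
    p <- if (is_case[i]) eth_p_case else eth_p_ctrl
    sample(names(p), 1L, prob = p)
  }, character(1))
  smk_p_case <- c(never = 0.65, former = 0.28, current = 0.07)
  smk_p_ctrl <- c(never = 0.50, former = 0.38, current = 0.12)
  smoking <- vapply(seq_len(ns), function(i) {
    p <- if (is_case[i]) smk_p_case else smk_p_ctrl
    sample(names(p), 1L, prob = p)
  }, character(1))
  draw_year <- ifelse(wave == 1L, sample(2000:2007, ns, replace = TRUE),
                      sample(2011:2018, ns, replace = TRUE))
  # disease severity latent drives LEDD / HY / UPDRS-III jointly (cases only)
  sev <- stats::rnorm(ns)
  ledd <- ifelse(is_case,
                 round(stats::qgamma(stats::pnorm(0.6 * sev +
                                                    0.8 * stats::rnorm(ns)),
                                     shape = 2, scale = 300)),
                 0)
  hy <- ifelse(is_case,
               pmin(4, pmax(1, round(2 + 0.8 * sev + 0.5 * stats::rnorm(ns)))),
               NA_real_)
  updrs3 <- ifelse(is_case,
                   pmax(0, round(22 + 10 * sev + 6 * stats::rnorm(ns))),
                   NA_real_)
  data.frame(subject_id = subject_id, wave = wave, status = status,
             age = age, gender = gender, ethnicity = ethnicity,
             smoking = smoking, draw_year = draw_year,
             ledd = ledd, hy = hy, updrs3 = updrs3,
             stringsAsFactors = FALSE)
}

simulate_injection_plan <- function(cfg, subjects) {
  ns <- nrow(subjects)
  n_batches <- cfg$n_batches %||% ceiling(ns / cfg$batch_size)
  # subjects randomly sorted into batches
  shuffled <- sample(subjects$subject_id)
  batch_of <- rep(seq_len(n_batches), each = cfg$batch_size,
                  length.out = ns)
  run_of_batch <- rep(seq_len(cfg$n_runs),
                      each = ceiling(n_batches / cfg$n_runs),
                      length.out = n_batches)
  rows <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    subj_b <- shuffled[batch_of == b]
    run <- run_of_batch[b]
    qc_id <- sprintf("QC_R%d", run)
    # QC positions interleave start / interior / end of the batch
    study <- data.frame(
      subject_id = rep(subj_b, each = cfg$n_replicate_injections),
      role = "study",
      replicate_index = rep(seq_len(cfg$n_replicate_injections),
                            times = length(subj_b)),
      stringsAsFactors = FALSE)
    qc <- data.frame(subject_id = qc_id, role = "qc",
                     replicate_index = seq_len(cfg$qc_per_batch),
                     stringsAsFactors = FALSE)
    nstudy <- nrow(study)
    # QC injections at evenly spaced slots through the batch (start .. end)
    qc_slots <- round(seq(0, nstudy, length.out = cfg$qc_per_batch))
    pieces <- list()
    prev <- 0L
    for (k in seq_len(cfg$qc_per_batch)) {
      upto <- qc_slots[k]
      if (upto > prev) pieces[[length(pieces) + 1L]] <- study[(prev + 1L):upto, ]
      pieces[[length(pieces) + 1L]] <- qc[k, ]
      prev <- upto
    }
    if (prev < nstudy) pieces[[length(pieces) + 1L]] <- study[(prev + 1L):nstudy, ]
    dfb <- do.call(rbind, pieces)
    dfb$batch <- b
    dfb$run <- run
    rows[[b]] <- dfb
  }
  plan <- do.call(rbind, rows)
  plan$order <- seq_len(nrow(plan))
  plan$injection_id <- sprintf("INJ%05d", plan$order)
  rownames(plan) <- NULL
  plan[, c("injection_id", "subject_id", "role", "replicate_index",
           "batch", "run", "order")]
}

simulate_truth <- function(cfg) {
  cols <- c("c18neg", "hilicpos")
  per <- cfg$n_features_per_column
  out <- vector("list", length(cols))
  met_counter <- 0L
  for (ci in seq_along(cols)) {
    col <- cols[ci]
    mz <- sort(stats::runif(per, 85, if (col == "c18neg") 850 else 1200))
    rt <- stats::runif(per, 20, 600)
    mu <- stats::rnorm(per, 14, 2)
    true_log2fc <- numeric(per)
    n_true <- round(cfg$frac_true_effects * per)
    idx_true <- if (n_true > 0) sample.int(per, n_true) else integer(0)
    if (n_true > 0) {
      mag <- stats::runif(n_true, cfg$effect_log2fc_range[1],
                          cfg$effect_log2fc_range[2])
      true_log2fc[idx_true] <- mag * sample(c(-1, 1), n_true, replace = TRUE)
    }
    ledd_slope <- numeric(per)
    n_med <- min(cfg$n_medication_features, per)
    idx_med <- if (n_med > 0) sample.int(per, n_med) else integer(0)
    if (n_med > 0)
      ledd_slope[idx_med] <- stats::runif(n_med, 0.0008, 0.002) *
        sample(c(-1, 1), n_med, replace = TRUE, prob = c(0.2, 0.8))
    age_slope <- numeric(per)
    n_age <- min(cfg$n_age_features, per)
    idx_age <- if (n_age > 0) sample.int(per, n_age) else integer(0)
    if (n_age > 0)
      age_slope[idx_age] <- stats::runif(n_age, 0.01, 0.03) *
        sample(c(-1, 1), n_age, replace = TRUE)
    is_junk <- rep(FALSE, per)
    n_junk <- min(cfg$n_junk_cv_features, per)
    if (n_junk > 0) is_junk[sample.int(per, n_junk)] <- TRUE
    mapped <- rep(NA_character_, per)
    n_map <- round(cfg$frac_mapped * per)
    if (n_map > 0) {
      idx_map <- sample.int(per, n_map)
      mapped[idx_map] <- sprintf("MET%05d", met_counter + seq_len(n_map))
      met_counter <- met_counter + n_map
    }
    out[[ci]] <- data.frame(
      feature_id = sprintf("%s_F%04d", col, seq_len(per)),
      column = col, mz = mz, rt = rt, mu = mu,
      true_log2fc = true_log2fc,
      is_medication_linked = ledd_slope != 0,
      ledd_slope = ledd_slope,
      age_slope = age_slope,
      is_junk = is_junk,
      mapped_metabolite_id = mapped,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic two-wave metabolomics cohort
#'
#' Simulates subjects, an injection plan (batches, runs, triplicates,
#' pooled-QC positions) and a raw feature-intensity table under an additive
#' log2-scale generative model: baseline + planted case effect + age slope +
#' LEDD-linked medication effect (cases only) + per-feature batch and run
#' offsets + within-run drift + subject-level biological residual +
#' replicate injection noise.  Linear intensities below the feature's
#' detection-limit quantile are recorded as 0.  QC injections share one
#' pooled profile per run (no subject-level biology).
#'
#' @param cfg a [cohort_config()].
#' @return list with elements `table` (a [feature_table()] containing both
#'   chromatography columns), `subjects` (subject metadata data.frame) and
#'   `truth` (per-feature ground-truth data.frame carrying the planted
#'   log2FC, medication / age / junk flags and mapped metabolite ids, with
#'   the per-feature batch-offset matrix as attribute `"batch_offsets"`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    subjects <- simulate_subjects(cfg)
    plan <- simulate_injection_plan(cfg, subjects)
    truth <- simulate_truth(cfg)

    g <- nrow(truth)
    n_inj <- nrow(plan)
    n_batches <- max(plan$batch)
    batch_off <- matrix(stats::rnorm(g * n_batches, 0, cfg$batch_sd),
                        g, n_batches,
                        dimnames = list(truth$feature_id, NULL))
    run_off <- matrix(stats::rnorm(g * cfg$n_runs, 0, cfg$run_sd),
                      g, cfg$n_runs)
    drift <- stats::rnorm(g, 0, cfg$drift_slope)

    # subject-level component: biology + planted effects
    ns <- nrow(subjects)
    case <- as.numeric(subjects$status == "case")
    age_c <- subjects$age - mean(subjects$age)
    subj_mat <- matrix(stats::rnorm(g * ns, 0, cfg$residual_sd), g, ns,
                       dimnames = list(truth$feature_id, subjects$subject_id))
    subj_mat <- subj_mat +
      outer(truth$true_log2fc, case) +
      outer(truth$age_slope, age_c) +
      outer(truth$ledd_slope, subjects$ledd * case)

    # normalized within-run injection order in [-0.5, 0.5]
    ord_norm <- numeric(n_inj)
    for (r in seq_len(cfg$n_runs)) {
      sel <- plan$run == r
      o <- plan$order[sel]
      ord_norm[sel] <- (o - min(o)) / max(1, diff(range(o))) - 0.5
    }

    rep_sd <- ifelse(truth$is_junk, log2_sd_for_cv(cfg$junk_cv),
                     log2_sd_for_cv(cfg$replicate_cv))
    x <- matrix(stats::rnorm(g * n_inj), g, n_inj) * rep_sd
    x <- x + truth$mu +
      batch_off[, plan$batch, drop = FALSE] +
      run_off[, plan$run, drop = FALSE] +
      drift %o% ord_norm
    is_study <- plan$role == "study"
    subj_idx <- match(plan$subject_id, subjects$subject_id)
    x[, is_study] <- x[, is_study] +
      subj_mat[, subj_idx[is_study], drop = FALSE]

    linear <- 2^x
    if (cfg$lod_quantile > 0) {
      lod <- apply(linear, 1, stats::quantile, probs = cfg$lod_quantile)
      linear[linear < lod] <- 0
    }
    dimnames(linear) <- list(truth$feature_id, plan$injection_id)

    features <- truth[, c("feature_id", "column", "mz", "rt")]
    tab <- feature_table(features, plan, linear)
    truth_out <- truth
    attr(truth_out, "batch_offsets") <- batch_off
    list(table = tab, subjects = subjects, truth = truth_out)
  })
}

#' Generate a matching reference library and pathway sets
#'
#' Every mapped feature in the truth table receives a reference metabolite
#' whose monoisotopic mass back-computes the feature's observed m/z exactly
#' (0 ppm) under the column's default adduct (`[M-H]-` for C18 negative,
#' `[M+H]+` for HILIC positive); library retention times equal the feature's
#' RT so tier-1 (mass + RT) annotation is attainable.  Pathway sets include
#' one pathway enriched for true-effect metabolites by construction plus
#' null pathways drawn from null metabolites.
#'
#' @param truth truth data.frame from [generate_cohort()].
#' @param cfg the same [cohort_config()].
#' @param n_null_pathways number of null pathways (>= 3).
#' @param pathway_size metabolites per pathway.
#' @param enriched_frac fraction of the enriched pathway drawn from
#'   true-effect metabolites (>= 0.5).
#' @return list with `library` (data.frame: metabolite_id, name,
#'   monoisotopic_mass, rt_c18, rt_hilic) and `pathways` (named list of
#'   metabolite-id character vectors, writable with [write_gmt()]).
#' @export
generate_reference_and_pathways <- function(truth, cfg, n_null_pathways = 5,
                                            pathway_size = 10,
                                            enriched_frac = 0.7) {
  stopifnot(n_null_pathways >= 3, enriched_frac >= 0.5)
  mapped <- truth[!is.na(truth$mapped_metabolite_id), , drop = FALSE]
  if (nrow(mapped) == 0) stopf("truth table has no mapped features")
  proton <- 1.007276
  mass <- ifelse(mapped$column == "c18neg", mapped$mz + proton,
                 mapped$mz - proton)
  lib <- data.frame(
    metabolite_id = mapped$mapped_metabolite_id,
    name = sprintf("Metabolite %s", sub("^MET", "", mapped$mapped_metabolite_id)),
    monoisotopic_mass = mass,
    rt_c18 = ifelse(mapped$column == "c18neg", mapped$rt, NA_real_),
    rt_hilic = ifelse(mapped$column == "hilicpos", mapped$rt, NA_real_),
    stringsAsFactors = FALSE)

  with_seed(child_seed(cfg$seed, 101), {
    true_mets <- mapped$mapped_metabolite_id[mapped$true_log2fc != 0]
    null_mets <- mapped$mapped_metabolite_id[mapped$true_log2fc == 0]
    n_true_in <- max(ceiling(enriched_frac * pathway_size),
                     ceiling(pathway_size / 2))
    n_true_in <- min(n_true_in, length(true_mets))
    paths <- list()
    if (n_true_in > 0) {
      ## cap the null complement so the enriched fraction holds by
      ## construction even when few true-effect metabolites are mapped
      n_null_in <- min(pathway_size - n_true_in,
                       floor(n_true_in * (1 - enriched_frac) / enriched_frac),
                       length(null_mets))
      paths$pathway_enriched <- c(sample(true_mets, n_true_in),
                                  sample(null_mets, n_null_in))
    }  # null cohorts (no planted effects) get null pathways only
    for (k in seq_len(n_null_pathways)) {
      paths[[sprintf("pathway_null_%02d", k)]] <-
        sample(null_mets, min(pathway_size, length(null_mets)))
    }
    list(library = lib, pathways = paths)
  })
}

#' Generate an external-study summary table
#'
#' Simulates the situation where only per-metabolite fold changes, p-values
#' and the total sample size of an external case-control study are
#' available.  The external log2 fold change is correlated with the internal
#' planted effect at `cfg$external_rho`; its p-value derives from a Wald
#' statistic at the external sample size.
#'
#' @param truth truth data.frame from [generate_cohort()].
#' @param cfg the same [cohort_config()].
#' @return data.frame: `metabolite`, `fold_change` (linear), `p_value`
#'   (in (0, 1]), `n`.
#' @export
generate_external_summary <- function(truth, cfg) {
  mapped <- truth[!is.na(truth$mapped_metabolite_id), , drop = FALSE]
  with_seed(child_seed(cfg$seed, 202), {
    rho <- cfg$external_rho
    l_ext <- rho * mapped$true_log2fc +
      cfg$external_noise_sd * stats::rnorm(nrow(mapped))
    se <- 4 / sqrt(cfg$external_n)
    p <- 2 * stats::pnorm(-abs(l_ext) / se)
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    data.frame(metabolite = mapped$mapped_metabolite_id,
               fold_change = 2^l_ext,
               p_value = p,
               n = cfg$external_n,
               stringsAsFactors = FALSE)
  })
}

#' Write the ground-truth table as TSV
#'
#' Per-feature batch offsets are flattened into `batch_offset_<k>` columns.
#'
#' @param truth truth data.frame from [generate_cohort()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  off <- attr(truth, "batch_offsets")
  out <- as.data.frame(truth)
  if (!is.null(off)) {
    colnames(off) <- sprintf("batch_offset_%d", seq_len(ncol(off)))
    out <- cbind(out, as.data.frame(off, check.names = FALSE))
  }
  write_tsv_file(out, path)
}
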