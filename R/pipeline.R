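#' Pipeline configuration
#'
#' Nested configuration for the end-to-end analysis.  Any part can be
#' overridden; unspecified values take module defaults.  Thresholds:
#' MWAS FDR 0.05, replication per-wave p 0.05 (sensitivity 0.10), log2FC
#' tiers 0.25 / 0.5, network |r| 0.2, annotation ppm 5 / 10 with 30 s RT,
#' permutation count B.
#'
#' @param seed global seed recorded in every output.
#' @param scale `"full"` or `"test"` synthetic-cohort scale (when
#'   simulating).
#' @param cohort [cohort_config()] or NULL to derive from `scale`/`seed`.
#' @param preprocess [preprocess_config()].
#' @param fdr_max MWAS significance threshold (BH FDR).
#' @param replication thresholds list for [classify_replication()].
#' @param network_min_abs_r correlation-network threshold.
#' @param ppm_tol_tier1,ppm_tol_tier2,rt_tol annotation tolerances.
#' @param permutation_B pathway permutation count.
#' @param paths named list of input paths (feature table, metadata,
#'   library TSV, pathways GMT, external summary) when not simulating.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, scale = c("test", "full"),
                            cohort = NULL,
                            preprocess = preprocess_config(),
                            fdr_max = 0.05,
                            replication = list(per_wave_p_max = 0.05,
                                               log2fc_tier1 = 0.25,
                                               log2fc_tier2 = 0.50),
                            network_min_abs_r = 0.2,
                            ppm_tol_tier1 = 5, ppm_tol_tier2 = 10,
                            rt_tol = 30,
                            permutation_B = 999,
                            paths = list()) {
  scale <- match.arg(scale)
  if (is.null(cohort)) {
    cohort <- if (scale == "test") cohort_config_test(seed = seed)
    else cohort_config(seed = seed)
  }
  structure(list(seed = seed, scale = scale, cohort = cohort,
                 preprocess = preprocess, fdr_max = fdr_max,
                 replication = replication,
                 network_min_abs_r = network_min_abs_r,
                 ppm_tol_tier1 = ppm_tol_tier1,
                 ppm_tol_tier2 = ppm_tol_tier2, rt_tol = rt_tol,
                 permutation_B = permutation_B, paths = paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file; top-level keys mirror [pipeline_config()]
#'   arguments, with `cohort` holding [cohort_config()] overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- NULL
  if (!is.null(raw$cohort)) {
    maker <- if (identical(raw$scale, "full")) cohort_config
    else cohort_config_test
    cohort <- do.call(maker, raw$cohort)
  }
  args <- raw[setdiff(names(raw), c("cohort", "preprocess"))]
  args$cohort <- cohort
  if (!is.null(raw$preprocess))
    args$preprocess <- do.call(preprocess_config, raw$preprocess)
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> MWAS -> annotation ->
#' pathway enrichment -> correlation network -> external validation, writes
#' all tabular outputs under `out_dir` and a JSON run manifest (seed,
#' parameters, step timings).  Reruns with the same configuration and seed
#' reproduce all numeric outputs exactly.  A missing pathway file (or an
#' annotation step without hits) downgrades that stage to a logged warning;
#' other outputs are written regardless.
#'
#' @param config [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return list bundle: `cohort`, `processed`, `mwas`, `hits`, `pathways`,
#'   `network`, `external`, `manifest`.
#' @export
run_full <- function(config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  timings <- list()
  clock <- function(name, expr) {
    s <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    val
  }

  have_inputs <- length(config$paths) > 0 &&
    !is.null(config$paths$feature_table)
  if (have_inputs) {
    cohort <- clock("load", {
      list(table = read_feature_table(config$paths$feature_table,
                                      config$paths$injections),
           subjects = read_subjects(config$paths$subjects),
           truth = NULL)
    })
    ref <- if (!is.null(config$paths$library))
      list(library = read_tsv_file(config$paths$library),
           pathways = if (!is.null(config$paths$pathways) &&
                          file.exists(config$paths$pathways))
             read_gmt(config$paths$pathways) else NULL)
    else list(library = NULL, pathways = NULL)
    external <- if (!is.null(config$paths$external))
      utils::read.csv(config$paths$external, stringsAsFactors = FALSE)
    else NULL
  } else {
    cohort <- clock("simulate", generate_cohort(config$cohort))
    ref <- clock("reference", generate_reference_and_pathways(cohort$truth,
                                                              config$cohort))
    external <- clock("external_summary",
                      generate_external_summary(cohort$truth, config$cohort))
  }

  prep <- clock("preprocess",
                preprocess(cohort$table, cohort$subjects, config$preprocess))
  mwas <- clock("mwas", run_mwas(prep$matrix, cohort$subjects,
                                 replication = config$replication))

  sig_features <- mwas$feature_id[!is.na(mwas$fdr_limma) &
                                    mwas$fdr_limma < config$fdr_max]

  hits <- NULL
  pathways <- NULL
  if (!is.null(ref$library)) {
    hits <- clock("annotate",
                  match_features(prep$matrix$features, ref$library,
                                 ppm_tol_tier1 = config$ppm_tol_tier1,
                                 ppm_tol_tier2 = config$ppm_tol_tier2,
                                 rt_tol = config$rt_tol))
    if (!is.null(ref$pathways) && nrow(hits)) {
      wm <- build_weight_map(hits)
      pathways <- clock("pathways",
                        pathway_permutation_test(wm, sig_features,
                                                 ref$pathways,
                                                 B = config$permutation_B,
                                                 seed = child_seed(config$seed, 7)))
    } else {
      warning("pathway stage skipped: no pathway sets or no annotation hits")
    }
  }

  network <- clock("network", {
    if (length(sig_features) >= 2) {
      correlation_network(prep$matrix, sig_features,
                          min_abs_r = config$network_min_abs_r)
    } else data.frame(feature_a = character(0), feature_b = character(0),
                      r = numeric(0))
  })

  external_res <- NULL
  if (!is.null(external) && !is.null(hits) && nrow(hits)) {
    external_res <- clock("validate_external", {
      internal <- internal_summary_for_validation(mwas, hits,
                                                  cohort$subjects)
      if (nrow(internal)) cross_study_meta(internal, external) else NULL
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("metabomwas")),
    seed = config$seed,
    scale = config$scale,
    thresholds = list(fdr_max = config$fdr_max,
                      replication = config$replication,
                      network_min_abs_r = config$network_min_abs_r,
                      ppm = c(config$ppm_tol_tier1, config$ppm_tol_tier2),
                      rt_tol = config$rt_tol,
                      permutation_B = config$permutation_B),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  bundle <- list(cohort = cohort, processed = prep, mwas = mwas,
                 hits = hits, pathways = pathways, network = network,
                 external = external_res, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

## internal per-metabolite summary (FC, p, n) from MWAS rows via top
## annotation hit, for the external-validation join
internal_summary_for_validation <- function(mwas, hits, subjects) {
  if (!nrow(hits)) return(data.frame())
  best <- hits[!duplicated(hits$feature_id), , drop = FALSE]  # sorted by |ppm|
  m <- merge(mwas, best[, c("feature_id", "metabolite_id")],
             by = "feature_id")
  m <- m[order(m$p_limma), , drop = FALSE]
  m <- m[!duplicated(m$metabolite_id), , drop = FALSE]
  data.frame(metabolite = m$metabolite_id,
             fold_change = 2^m$log2fc,
             p_value = m$p_limma,
             n = nrow(subjects),
             stringsAsFactors = FALSE)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_tsv_file(bundle$mwas, p("mwas_results.tsv"))
  write_processed_matrix(bundle$processed$matrix, p("processed_matrix.tsv"))
  write_tsv_file(bundle$processed$cv_report$summary, p("qc_cv_summary.tsv"))
  if (!is.null(bundle$hits)) write_tsv_file(bundle$hits, p("annotation_hits.tsv"))
  if (!is.null(bundle$pathways))
    write_tsv_file(bundle$pathways, p("pathway_results.tsv"))
  write_network(bundle$network, p("network_edges.tsv"), p("network.graphml"))
  if (!is.null(bundle$external))
    write_tsv_file(bundle$external, p("external_validation.tsv"))
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summary report of a pipeline run
#'
#' Recomputes (never caches) the headline counts from the result tables:
#' features tested, BH-FDR hits, fold-change tier counts, replicated
#' counts, phenotype-associated counts, enriched pathways, network size,
#' and the external-validation labels.
#'
#' @param bundle result of [run_full()].
#' @param fdr_max significance threshold used for the counts.
#' @return list of counts and tables (class `mwas_report`).
#' @export
export_report <- function(bundle, fdr_max = 0.05) {
  m <- bundle$mwas
  sig <- !is.na(m$fdr_limma) & m$fdr_limma < fdr_max
  rep_tier <- m$replication_tier
  counts <- list(
    n_features = nrow(m),
    n_fdr_sig = sum(sig),
    n_fdr_sig_fc50 = sum(sig & abs(m$log2fc) > 0.5),
    n_fdr_sig_fc25 = sum(sig & abs(m$log2fc) > 0.25),
    n_replicated = sum(rep_tier != "not_replicated"),
    n_replicated_fc50 = sum(rep_tier == "replicated_fc50"),
    n_ledd_fdr_sig = if ("ledd_fdr" %in% names(m))
      sum(m$ledd_fdr < fdr_max, na.rm = TRUE) else NA_integer_,
    n_pathways_sig = if (!is.null(bundle$pathways))
      sum(bundle$pathways$fdr < fdr_max) else NA_integer_,
    n_network_edges = nrow(bundle$network))
  validation <- if (!is.null(bundle$external))
    bundle$external[, c("metabolite", "label")] else NULL
  structure(list(counts = counts, validation = validation,
                 seed = bundle$manifest$seed), class = "mwas_report")
}

#' @export
print.mwas_report <- function(x, ...) {
  cat("MWAS run report (seed", x$seed, ")\n")
  for (nm in names(x$counts)) cat(sprintf("  %-18s %s\n", nm, x$counts[[nm]]))
  if (!is.null(x$validation)) {
    cat("  external validation labels:\n")
    print(table(x$validation$label))
  }
  invisible(x)
}

#' Command-line interface
#'
#' Subcommand front-end for scripted use:
#' `simulate`, `run-all`, `report`.  Flags: `--config <json>`,
#' `--seed <int>`, `--out-dir <dir>`, `--scale test|full`.
#'
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return exit status, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: metabomwas <simulate|run-all|report> [--config c.json] ",
            "[--seed N] [--out-dir DIR] [--scale test|full]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out_dir <- opt("--out-dir", "metabomwas_out")
  scale <- opt("--scale", "test")
  cfg_path <- opt("--config")
  config <- if (!is.null(cfg_path)) read_pipeline_config(cfg_path)
  else pipeline_config(seed = seed, scale = scale)

  if (cmd == "simulate") {
    cohort <- generate_cohort(config$cohort)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(cohort$table,
                        file.path(out_dir, "feature_table.tsv"),
                        file.path(out_dir, "injections.tsv"))
    write_subjects(cohort$subjects, file.path(out_dir, "subjects.tsv"))
    write_truth(cohort$truth, file.path(out_dir, "truth.tsv"))
    message("simulated cohort written to ", out_dir)
  } else if (cmd == "run-all") {
    bundle <- run_full(config, out_dir = out_dir)
    print(export_report(bundle, config$fdr_max))
    message("outputs written to ", out_dir)
  } else if (cmd == "report") {
    bundle <- run_full(config, out_dir = NULL)
    print(export_report(bundle, config$fdr_max))
  } else {
    message("unknown subcommand: ", cmd)
    return(invisible(1L))
  }
  invisible(0L)
}
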